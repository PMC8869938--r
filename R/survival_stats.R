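# Endpoint extraction and evaluation statistics. Kaplan-Meier estimation,
# Cox proportional-hazards fits and the log-rank test are delegated to the
# survival package; the censoring-aware concordance index is implemented
# here with its pair-count breakdown exposed, because the per-pair rules are
# part of the package's contract (they must agree exactly with a brute-force
# pair enumerator).

#' Extract a survival endpoint from a cohort
#'
#' @param cohort Cohort data.frame.
#' @param endpoint "rfs" (relapse-free survival: surgery to first recurrence
#'   or disease death) or "os" (disease-specific overall survival).
#' @return data.frame with numeric `time` (months) and integer `event`.
#' @export
survival_endpoint <- function(cohort, endpoint = c("rfs", "os")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "rfs") {
    data.frame(time = cohort$rfs_time_months, event = cohort$rfs_event)
  } else {
    data.frame(time = cohort$os_time_months, event = cohort$os_event)
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate with Greenwood variance and pointwise
#' log-log confidence intervals. Censorings tied with an event time are
#' processed after the events at that time (the standard convention). The
#' returned object keeps only the event times (where the step function
#' drops) plus the maximal observed time for extrapolation detection.
#'
#' @param time Positive follow-up times in months.
#' @param event 0/1 (or logical) event indicators.
#' @param conf_level Confidence level for the pointwise intervals.
#' @return An object of class `km_curve` with fields `event_times`,
#'   `survival`, `at_risk`, `n_event`, `greenwood_var`, `ci_low`, `ci_high`,
#'   `max_time`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  event <- as.integer(event)
  stopifnot(length(time) == length(event), all(event %in% 0:1))
  if (length(time) == 0) stop("no survival data")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative")
  }
  if (all(time == 0)) stop("all follow-up times are zero")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  keep <- fit$n.event > 0
  structure(list(
    event_times = fit$time[keep],
    survival = fit$surv[keep],
    at_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    # survfit std.err is the SE of log S (Greenwood sum); back-transform
    greenwood_var = (fit$surv[keep] * fit$std.err[keep])^2,
    ci_low = fit$lower[keep],
    ci_high = fit$upper[keep],
    max_time = max(fit$time),
    n = length(time),
    n_events = sum(event),
    conf_level = conf_level
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, follow-up <= %.1f months\n",
              x$n, x$n_events, x$max_time))
  if (length(x$event_times) > 0) {
    cat(sprintf("  S at last event time %.1f: %.3f (%.0f%% CI %.3f-%.3f)\n",
                max(x$event_times), x$survival[length(x$survival)],
                100 * x$conf_level,
                x$ci_low[length(x$ci_low)], x$ci_high[length(x$ci_high)]))
  }
  invisible(x)
}

#' Survival probability at a time point
#'
#' Step-function lookup of the product-limit estimate, e.g. the five-year
#' rate at t = 60 months. Requests beyond the last observed follow-up return
#' the last step value with an extrapolation warning.
#'
#' @param curve A `km_curve`.
#' @param t Non-negative time in months.
#' @param conf Also return the pointwise CI at the same step?
#' @return The survival probability, or a named vector
#'   `c(rate, ci_low, ci_high)` when `conf = TRUE`.
#' @export
survival_at <- function(curve, t, conf = FALSE) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.finite(t) || t < 0) stop("t must be non-negative")
  if (t > curve$max_time) {
    warning(sprintf("t = %g is beyond the last observed time %g; returning the last step value",
                    t, curve$max_time))
  }
  idx <- findInterval(t, curve$event_times)
  rate <- if (idx == 0) 1 else curve$survival[idx]
  if (!conf) return(rate)
  c(rate = rate,
    ci_low = if (idx == 0) 1 else curve$ci_low[idx],
    ci_high = if (idx == 0) 1 else curve$ci_high[idx])
}

#' Univariate Cox proportional-hazards fit
#'
#' Single-covariate partial-likelihood fit with Efron (default) or Breslow
#' tie handling, Wald confidence interval and p-value. Degenerate covariates
#' are an explicit error; monotone-likelihood non-convergence (e.g. perfect
#' separation) is flagged on the result rather than returned as silent
#' numbers.
#'
#' @param time,event Survival endpoint (months, 0/1).
#' @param covariate Numeric covariate vector; NAs excluded pairwise.
#' @param ties "efron" or "breslow".
#' @param coding Free-text description of the covariate coding, stored on
#'   the fit.
#' @param conf_level Wald CI level.
#' @return An object of class `cox_fit` with `beta`, `se`, `hr`, `ci95`,
#'   `p_value`, `n`, `n_events`, `ties`, `covariate_coding`, `converged`.
#' @export
cox_fit <- function(time, event, covariate, ties = c("efron", "breslow"),
                    coding = "numeric as supplied", conf_level = 0.95) {
  ties <- match.arg(ties)
  event <- as.integer(event)
  keep <- !is.na(time) & !is.na(event) & !is.na(covariate)
  time <- time[keep]; event <- event[keep]; covariate <- covariate[keep]
  if (length(unique(covariate)) < 2) {
    stop("covariate is constant after NA removal; no Cox fit possible")
  }
  if (sum(event) < 1) stop("no events; no Cox fit possible")

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik converged",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    ci95 = c(low = exp(beta - z * se), high = exp(beta + z * se)),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = fit$n, n_events = fit$nevent,
    ties = ties, covariate_coding = coding,
    converged = converged
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$ties, x$hr, x$ci95[["low"]], x$ci95[["high"]], x$p_value))
  cat(sprintf("  n = %d, events = %d; coding: %s%s\n", x$n, x$n_events,
              x$covariate_coding,
              if (x$converged) "" else " [WARNING: did not converge]"))
  invisible(x)
}

#' Ordinal-group Cox fit
#'
#' Encodes the risk-group label as a single integer covariate (1 for the
#' least severe level, incrementing by severity rank) and fits a univariate
#' Cox model, so the hazard ratio is per one-step increase in risk group —
#' the single-HR summary reported per classifier. Levels absent from the
#' data are skipped in the coding (the remaining ranks stay consecutive) and
#' recorded on the fit.
#'
#' @param labels Group labels.
#' @param time,event Survival endpoint.
#' @param levels Severity-ordered level set; defaults to the sorted unique
#'   labels. Use [scheme_levels()] for the shipped schemes.
#' @param ties Passed to [cox_fit()].
#' @return A `cox_fit` whose `covariate_coding` documents the integer map.
#' @export
cox_ordinal_by_group <- function(labels, time, event, levels = NULL,
                                 ties = c("efron", "breslow")) {
  if (is.null(levels)) levels <- sort(unique(stats::na.omit(labels)))
  present <- levels[levels %in% labels]
  if (length(present) < 2) stop("need >= 2 distinct groups for an ordinal fit")
  score <- match(labels, present)
  coding <- paste(sprintf("%s=%d", present, seq_along(present)),
                  collapse = ", ")
  cox_fit(time, event, score, ties = ties,
          coding = paste0("ordinal group score: ", coding))
}

#' Ordinal risk score for a label vector
#'
#' @param labels Group labels (NA allowed).
#' @param levels Severity-ordered levels.
#' @return Integer scores (1 = least severe present in `levels`).
#' @export
ordinal_score <- function(labels, levels) {
  match(labels, levels)
}

#' Censoring-aware concordance index
#'
#' Harrell-type concordance between risk scores and censored survival times.
#' A pair is permissible iff the smaller time belongs to an event (for tied
#' times, iff exactly one member is an event, the event member counting as
#' the shorter-lived); a permissible pair is concordant when the
#' shorter-lived patient carries the higher score, and score ties contribute
#' 0.5. The pair counts are exposed so the Goodman-Kruskal gamma variant
#' ((C - D)/(C + D), rescaled to \[0,1\]) can be derived from the same
#' enumeration.
#'
#' @param scores Numeric risk scores (higher = predicted worse outcome).
#' @param time,event Survival endpoint.
#' @return An object of class `concordance_result` with `c_index`,
#'   `concordant`, `discordant`, `tied`, `permissible`, `gamma_rescaled`.
#' @export
concordance_index <- function(scores, time, event) {
  event <- as.integer(event)
  keep <- !is.na(scores) & !is.na(time) & !is.na(event)
  scores <- scores[keep]; time <- time[keep]; event <- event[keep]
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; disc <- 0; tied <- 0
  for (i in seq_len(max(n - 1, 0))) {
    j <- (i + 1):n
    ti <- time[i]; tj <- time[j]
    # which member of the pair is the established shorter-lived event
    i_short <- (ti < tj & event[i] == 1L) |
      (ti == tj & event[i] == 1L & event[j] == 0L)
    j_short <- (tj < ti & event[j] == 1L) |
      (ti == tj & event[j] == 1L & event[i] == 0L)
    perm <- i_short | j_short
    if (!any(perm)) next
    short_score <- ifelse(i_short, scores[i], scores[j])
    long_score <- ifelse(i_short, scores[j], scores[i])
    conc <- conc + sum(perm & short_score > long_score)
    disc <- disc + sum(perm & short_score < long_score)
    tied <- tied + sum(perm & short_score == long_score)
  }
  permissible <- conc + disc + tied
  if (permissible == 0) {
    stop("no permissible pairs; concordance is undefined")
  }
  structure(list(
    c_index = (conc + 0.5 * tied) / permissible,
    concordant = conc, discordant = disc, tied = tied,
    permissible = permissible,
    gamma_rescaled = if (conc + disc > 0)
      ((conc - disc) / (conc + disc) + 1) / 2 else 0.5,
    n = n
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance: c-index = %.3f (%d concordant, %d discordant, %d tied of %d permissible pairs, n = %d)\n",
              x$c_index, x$concordant, x$discordant, x$tied, x$permissible,
              x$n))
  invisible(x)
}

#' K-group log-rank test
#'
#' @param labels Group labels (>= 2 distinct values after NA removal).
#' @param time,event Survival endpoint.
#' @return List with `chisq`, `df` (k - 1) and `p_value`.
#' @export
logrank_test <- function(labels, time, event) {
  keep <- !is.na(labels) & !is.na(time) & !is.na(event)
  labels <- labels[keep]; time <- time[keep]; event <- as.integer(event[keep])
  k <- length(unique(labels))
  if (k < 2) stop("log-rank test needs >= 2 groups")
  if (sum(event) < 1) stop("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  df <- k - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

# ---- univariate screens --------------------------------------------------

# The binary/ordinal codings used by the published univariate tables: the
# coded level is the one whose hazard the HR describes, relative to the
# reference. NE (and NA) map to NA and the fit is complete-case.
covariate_codings <- function() {
  bin <- function(col, one, zero) {
    force(col); force(one); force(zero)
    list(code = function(cohort) {
      x <- cohort[[col]]
      ifelse(x == one, 1, ifelse(x == zero, 0, NA_real_))
    }, coding = sprintf("%s: %s=1 vs %s=0", col, one, zero))
  }
  marker <- function(col) bin(col, "positive", "negative")
  list(
    age = list(code = function(cohort) as.numeric(cohort$age_years > 60),
               coding = "age: >60=1 vs <=60=0"),
    histology = bin("histology", "EEC", "NEEC"),
    grade = list(code = function(cohort)
      as.numeric(grade_binary(cohort$grade) == "high"),
      coding = "grade: high (G3)=1 vs low (G1+G2)=0"),
    myometrial_invasion = list(code = function(cohort)
      ifelse(cohort$myometrial_invasion == "NE", NA_real_,
             as.numeric(cohort$myometrial_invasion != "none")),
      coding = "myometrial invasion: yes=1 vs no=0"),
    lvsi = bin("lvsi", "positive", "negative"),
    figo_stage = list(code = function(cohort)
      match(cohort$figo_stage, c("IA", "IB", "II")),
      coding = "FIGO stage ordinal: IA=1, IB=2, II=3"),
    er = marker("er"), pr = marker("pr"), ecad = marker("ecad"),
    her2 = marker("her2"), arid1a = marker("arid1a"),
    pten = marker("pten"), l1cam = marker("l1cam"),
    ctnnb1 = bin("ctnnb1_exon3", "mutated", "wildtype")
  )
}

#' Univariate Cox screen over cohort covariates
#'
#' One complete-case univariate Cox fit per covariate for the requested
#' endpoint, using the standard codings (age >60 vs <=60, EEC vs NEEC, high
#' vs low grade, invasion yes vs no, LVSI positive vs negative, ordinal FIGO
#' stage, marker positive vs negative, CTNNB1 mutated vs wild type). NE
#' records are excluded per covariate. Covariates left with fewer than two
#' levels (or no events) get a no-fit entry instead of numbers.
#'
#' @param cohort Cohort data.frame (optionally pre-restricted to a
#'   subgroup).
#' @param covariates Names among `names(covariate_codings())`.
#' @param endpoint "rfs" or "os".
#' @return data.frame with one row per covariate: `covariate`, `n`,
#'   `n_events`, `hr`, `ci_low`, `ci_high`, `p_value`, `coding`, `note`
#'   ("ok" or the no-fit reason). The `cox_fit` objects are attached as the
#'   `fits` attribute.
#' @export
univariate_screen <- function(cohort,
                              covariates = names(covariate_codings()),
                              endpoint = c("rfs", "os")) {
  endpoint <- match.arg(endpoint)
  codings <- covariate_codings()
  unknown <- setdiff(covariates, names(codings))
  if (length(unknown) > 0) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  }
  sd <- survival_endpoint(cohort, endpoint)
  rows <- list(); fits <- list()
  for (cv in covariates) {
    x <- codings[[cv]]$code(cohort)
    fit <- tryCatch(
      cox_fit(sd$time, sd$event, x, coding = codings[[cv]]$coding),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      rows[[cv]] <- data.frame(covariate = cv, n = sum(!is.na(x)),
                               n_events = NA_integer_, hr = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               p_value = NA_real_,
                               coding = codings[[cv]]$coding,
                               note = fit, stringsAsFactors = FALSE)
    } else {
      fits[[cv]] <- fit
      rows[[cv]] <- data.frame(covariate = cv, n = fit$n,
                               n_events = fit$n_events, hr = fit$hr,
                               ci_low = fit$ci95[["low"]],
                               ci_high = fit$ci95[["high"]],
                               p_value = fit$p_value,
                               coding = codings[[cv]]$coding,
                               note = if (fit$converged) "ok" else
                                 "did not converge",
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "endpoint") <- endpoint
  out
}
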