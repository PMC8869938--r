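# Predictive-mean-matching imputation for the categorical molecular columns,
# with the modal value over many independently seeded runs taken as the
# completion. A categorical target with L observed levels is handled as L
# indicator regressions on the clinicopathological predictors: coefficients
# are drawn from their sampling distribution, the missing rows' predictions
# are matched to the k nearest complete-case predictions (squared distance
# summed over the L indicator dimensions), and one of the k donors' observed
# categories is donated. Donation guarantees every imputed value is a member
# of the observed category set.

#' Imputation configuration
#'
#' @param target_columns Categorical NE-capable columns to complete.
#' @param predictor_columns Clinicopathological predictors; categorical
#'   predictors enter as indicator columns. Rows with an NE predictor value
#'   are never used as donors.
#' @param n_runs Number of independently seeded PMM runs aggregated by mode.
#' @param k_donors Donor pool size per missing cell.
#' @param seed Master seed; run-level seeds are derived from it
#'   reproducibly.
#' @return List of class `imputation_config`.
#' @export
imputation_config <- function(target_columns = c("mmr_status", "p53_ihc",
                                                 "ctnnb1_exon3"),
                              predictor_columns = c("age_years", "histology",
                                                    "grade",
                                                    "myometrial_invasion",
                                                    "figo_stage", "lvsi"),
                              n_runs = 1000, k_donors = 5, seed = 1L) {
  stopifnot(n_runs >= 1, k_donors >= 1,
            all(target_columns %in% names(cohort_vocab())),
            all(predictor_columns %in% cohort_columns()))
  structure(list(target_columns = target_columns,
                 predictor_columns = predictor_columns,
                 n_runs = as.integer(n_runs),
                 k_donors = as.integer(k_donors),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# numeric design matrix (with intercept) over the predictor columns; rows
# with an NE categorical predictor become NA rows
impute_design <- function(cohort, predictor_columns) {
  vocab <- cohort_vocab()
  cols <- list(intercept = rep(1, nrow(cohort)))
  for (p in predictor_columns) {
    x <- cohort[[p]]
    if (p %in% names(vocab)) {
      lev <- setdiff(vocab[[p]], "NE")
      x[x == "NE"] <- NA
      for (l in lev[-1]) {
        cols[[paste0(p, ".", l)]] <- as.numeric(x == l)
      }
    } else {
      cols[[p]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

# one Bayesian-draw indicator regression; returns list(yhat_obs, yhat_mis)
# or NULL when the fit is degenerate
pmm_indicator_fit <- function(X_obs, y, X_mis) {
  qrX <- qr(X_obs)
  if (qrX$rank < 1) return(NULL)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y)
  df <- nrow(Xo) - ncol(Xo)
  if (df < 1) return(NULL)
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(Xo))), error = function(e) NULL)
  if (is.null(XtX_inv)) return(NULL)
  beta_draw <- fit$coefficients +
    drop(chol(sigma2 * XtX_inv + diag(1e-12, ncol(Xo))) %*%
           stats::rnorm(ncol(Xo)))
  list(yhat_obs = drop(Xo %*% fit$coefficients),
       yhat_mis = drop(Xm %*% beta_draw))
}

#' Single predictive-mean-matching run
#'
#' Completes every NE cell of the configured target columns once, using the
#' given run seed. Observed cells are never altered. When the predictor
#' design is degenerate for a target, imputation falls back to an
#' empirical-distribution donor draw and the fallback is recorded.
#'
#' @param cohort Cohort data.frame.
#' @param config An [imputation_config()].
#' @param run_seed Integer seed for this run.
#' @return List with `cohort` (completed) and `fallback` (character vector
#'   of targets that used the empirical fallback).
#' @export
pmm_single_run <- function(cohort, config, run_seed) {
  stopifnot(inherits(config, "imputation_config"))
  set.seed(as.integer(run_seed))
  X <- impute_design(cohort, config$predictor_columns)
  pred_ok <- stats::complete.cases(X)
  out <- cohort
  fallback <- character(0)

  for (tc in config$target_columns) {
    x <- cohort[[tc]]
    mis <- which(x == "NE")
    if (length(mis) == 0) next
    obs <- which(x != "NE" & pred_ok)
    if (length(obs) < config$k_donors) {
      stop(sprintf("target '%s': only %d complete cases, need >= k_donors = %d",
                   tc, length(obs), config$k_donors))
    }
    levels_obs <- intersect(cohort_vocab()[[tc]], unique(x[obs]))
    mis_fit <- mis[pred_ok[mis]]
    mis_nofit <- setdiff(mis, mis_fit)

    donated <- rep(NA_character_, length(mis))
    names(donated) <- as.character(mis)

    if (length(levels_obs) == 1) {
      donated[] <- levels_obs
    } else {
      d2 <- NULL
      if (length(mis_fit) > 0) {
        d2 <- matrix(0, nrow = length(mis_fit), ncol = length(obs))
        for (l in levels_obs) {
          f <- pmm_indicator_fit(X[obs, , drop = FALSE],
                                 as.numeric(x[obs] == l),
                                 X[mis_fit, , drop = FALSE])
          if (is.null(f)) { d2 <- NULL; break }
          d2 <- d2 + outer(f$yhat_mis, f$yhat_obs, function(a, b) (a - b)^2)
        }
      }
      if (!is.null(d2)) {
        for (m in seq_along(mis_fit)) {
          pool <- obs[order(d2[m, ])[seq_len(config$k_donors)]]
          donated[as.character(mis_fit[m])] <-
            x[pool[sample.int(length(pool), 1L)]]
        }
      } else if (length(mis_fit) > 0) {
        fallback <- c(fallback, tc)
        donated[as.character(mis_fit)] <-
          x[obs][sample.int(length(obs), length(mis_fit), replace = TRUE)]
      }
      if (length(mis_nofit) > 0) {
        # missing predictors: no prediction possible, empirical donor draw
        fallback <- unique(c(fallback, tc))
        donated[as.character(mis_nofit)] <-
          x[obs][sample.int(length(obs), length(mis_nofit), replace = TRUE)]
      }
    }
    out[[tc]][mis] <- donated[as.character(mis)]
  }
  list(cohort = out, fallback = unique(fallback))
}

#' Mode-aggregated predictive-mean-matching imputation
#'
#' Runs [pmm_single_run()] `n_runs` times with run seeds derived
#' reproducibly from the master seed and fills each missing cell with its
#' modal imputed value across runs. Modal ties are broken by the fixed
#' schema category order. Fully deterministic given `config$seed`.
#'
#' @param cohort Cohort data.frame.
#' @param config An [imputation_config()].
#' @return List with `cohort` (the modal completion) and `log`, a data.frame
#'   with one row per imputed cell: `patient_id`, `column`, `imputed`,
#'   `winning_votes`, `n_runs`, `tie_broken`, `votes` (all counts as
#'   "level:count" strings).
#' @export
pmm_mode_impute <- function(cohort, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$n_runs)

  cells <- list()
  for (tc in config$target_columns) {
    mis <- which(cohort[[tc]] == "NE")
    for (m in mis) cells[[paste(tc, m)]] <- list(column = tc, row = m,
                                                 votes = integer(0))
  }
  if (length(cells) == 0) {
    return(list(cohort = cohort,
                log = data.frame(patient_id = character(0),
                                 column = character(0),
                                 imputed = character(0),
                                 winning_votes = integer(0),
                                 n_runs = integer(0),
                                 tie_broken = logical(0),
                                 votes = character(0),
                                 stringsAsFactors = FALSE)))
  }

  votes <- lapply(cells, function(cell) {
    lev <- setdiff(cohort_vocab()[[cell$column]], "NE")
    stats::setNames(integer(length(lev)), lev)
  })
  for (r in seq_len(config$n_runs)) {
    run <- pmm_single_run(cohort, config, run_seeds[r])
    for (key in names(cells)) {
      cell <- cells[[key]]
      val <- run$cohort[[cell$column]][cell$row]
      votes[[key]][val] <- votes[[key]][val] + 1L
    }
  }

  out <- cohort
  log_rows <- lapply(names(cells), function(key) {
    cell <- cells[[key]]
    v <- votes[[key]]
    win <- names(v)[which.max(v)]  # which.max takes the first = schema order
    tie <- sum(v == max(v)) > 1
    out[[cell$column]][cell$row] <<- win
    data.frame(patient_id = as.character(cohort$patient_id[cell$row]),
               column = cell$column, imputed = win,
               winning_votes = max(v), n_runs = config$n_runs,
               tie_broken = tie,
               votes = paste(sprintf("%s:%d", names(v), v), collapse = ","),
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, log_rows)
  rownames(log) <- NULL
  list(cohort = out, log = log)
}
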