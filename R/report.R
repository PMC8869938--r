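# The analysis surface: per-classifier comparison reports (group
# distribution, per-group five-year rates, ordinal Cox fit, concordance,
# log-rank), reclassification transition matrices for Sankey rendering, the
# merged-intermediate biomarker screen, and the side-by-side evaluation of
# the CTNNB1-augmented three-tier proposal against the 2020 classifier.

#' Build a classifier comparison report
#'
#' Classifies the cohort under one scheme and assembles the per-group
#' distribution, Kaplan-Meier five-year (60-month) rates with pointwise CIs,
#' the ordinal-group Cox fit, the concordance index of the ordinal score,
#' and the k-group log-rank test, all computed on the same classified
#' records. Unclassifiable records are counted and excluded (run the
#' imputation module first for complete molecular data). Groups that are
#' empty or degenerate sub-statistics are reported as notes, not errors.
#'
#' @param cohort Cohort data.frame.
#' @param scheme One of "c2016", "promise", "c2020", "proposal".
#' @param endpoint "rfs" or "os".
#' @param labels Optional precomputed label vector aligned with the cohort
#'   (NA = unclassifiable); defaults to [classify_cohort()].
#' @return Object of class `classifier_report`: `scheme`, `endpoint`, `n`
#'   (classified), `n_unclassifiable`, `groups` (data.frame with `group`,
#'   `n`, `percent`, `n_events`, `rate_60m`, `rate_ci_low`, `rate_ci_high`),
#'   `cox` (a `cox_fit` or NULL), `concordance` (a `concordance_result` or
#'   NULL), `logrank` (list or NULL), `notes`.
#' @export
build_classifier_report <- function(cohort, scheme = c("c2020", "c2016",
                                                       "promise", "proposal"),
                                    endpoint = c("rfs", "os"),
                                    labels = NULL) {
  scheme <- match.arg(scheme)
  endpoint <- match.arg(endpoint)
  if (is.null(labels)) labels <- classify_cohort(cohort, scheme)$label
  stopifnot(length(labels) == nrow(cohort))
  sd <- survival_endpoint(cohort, endpoint)
  keep <- !is.na(labels)
  notes <- character(0)
  if (any(!keep)) {
    notes <- c(notes, sprintf("%d unclassifiable record(s) excluded",
                              sum(!keep)))
  }
  labels <- labels[keep]; sd <- sd[keep, , drop = FALSE]
  lev <- scheme_levels(scheme)
  present <- lev[lev %in% labels]
  if (length(present) < length(lev)) {
    notes <- c(notes, sprintf(
      "empty group(s) skipped in ordinal coding: %s",
      paste(setdiff(lev, present), collapse = ", ")))
  }

  groups <- do.call(rbind, lapply(lev, function(g) {
    sel <- labels == g
    if (!any(sel)) {
      return(data.frame(group = g, n = 0L, percent = 0, n_events = 0L,
                        rate_60m = NA_real_, rate_ci_low = NA_real_,
                        rate_ci_high = NA_real_, stringsAsFactors = FALSE))
    }
    rate <- tryCatch({
      km <- km_estimate(sd$time[sel], sd$event[sel])
      suppressWarnings(survival_at(km, 60, conf = TRUE))
    }, error = function(e) c(rate = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_))
    data.frame(group = g, n = sum(sel),
               percent = 100 * sum(sel) / length(labels),
               n_events = sum(sd$event[sel]),
               rate_60m = unname(rate[["rate"]]),
               rate_ci_low = unname(rate[["ci_low"]]),
               rate_ci_high = unname(rate[["ci_high"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL

  cox <- NULL; conc <- NULL; lr <- NULL
  if (length(present) >= 2 && sum(sd$event) >= 1) {
    cox <- tryCatch(cox_ordinal_by_group(labels, sd$time, sd$event,
                                         levels = lev),
                    error = function(e) {
                      notes <<- c(notes, paste("ordinal Cox:",
                                               conditionMessage(e)))
                      NULL
                    })
    conc <- tryCatch(concordance_index(ordinal_score(labels, present),
                                       sd$time, sd$event),
                     error = function(e) {
                       notes <<- c(notes, paste("concordance:",
                                                conditionMessage(e)))
                       NULL
                     })
    lr <- tryCatch(logrank_test(labels, sd$time, sd$event),
                   error = function(e) {
                     notes <<- c(notes, paste("log-rank:",
                                              conditionMessage(e)))
                     NULL
                   })
  } else {
    notes <- c(notes,
               "fewer than 2 groups or no events: distribution only")
  }

  structure(list(scheme = scheme, endpoint = endpoint,
                 n = length(labels), n_unclassifiable = sum(!keep),
                 groups = groups, cox = cox, concordance = conc,
                 logrank = lr, notes = notes),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Classifier report: %s, endpoint %s, n = %d classified (%d unclassifiable)\n",
              x$scheme, toupper(x$endpoint), x$n, x$n_unclassifiable))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-18s n = %3d (%5.1f%%), events = %3d, 60-month rate = %s\n",
                g$group[i], g$n[i], g$percent[i], g$n_events[i],
                if (is.na(g$rate_60m[i])) "NA" else
                  sprintf("%.1f%%", 100 * g$rate_60m[i])))
  }
  if (!is.null(x$cox)) {
    cat(sprintf("  ordinal Cox: HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                x$cox$hr, x$cox$ci95[["low"]], x$cox$ci95[["high"]],
                x$cox$p_value))
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("  c-index: %.2f\n", x$concordance$c_index))
  }
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chi-square %.2f on %d df, p = %.3g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p_value))
  }
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Reclassification transition matrix
#'
#' Contingency counts of patients between the groups of two classification
#' schemes — the data behind a Sankey reclassification diagram.
#'
#' @param labels_a,labels_b Aligned label vectors (records NA in either are
#'   dropped and counted).
#' @param levels_a,levels_b Optional level orders for the margins.
#' @return Object of class `transition_matrix`: `counts` (matrix),
#'   `row_marginals`, `col_marginals`, `n`, `n_dropped`.
#' @export
sankey_matrix <- function(labels_a, labels_b, levels_a = NULL,
                          levels_b = NULL) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must be aligned (same length)")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  if (is.null(levels_a)) levels_a <- sort(unique(a))
  if (is.null(levels_b)) levels_b <- sort(unique(b))
  counts <- table(factor(a, levels = levels_a),
                  factor(b, levels = levels_b))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  structure(list(counts = counts,
                 row_marginals = rowSums(counts),
                 col_marginals = colSums(counts),
                 n = sum(counts), n_dropped = sum(!keep)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix (%d patients, %d dropped):\n", x$n,
              x$n_dropped))
  print(x$counts)
  invisible(x)
}

#' Sankey plotting payload
#'
#' Serializes a transition matrix to the {nodes, links} structure common
#' Sankey renderers consume.
#'
#' @param tm A `transition_matrix`.
#' @param from_name,to_name Scheme names used to label the nodes.
#' @return List with `nodes` (data.frame: `name`) and `links` (data.frame:
#'   `source`, `target`, zero-based node indices, and `value`).
#' @export
sankey_payload <- function(tm, from_name = "from", to_name = "to") {
  stopifnot(inherits(tm, "transition_matrix"))
  from_levels <- rownames(tm$counts)
  to_levels <- colnames(tm$counts)
  nodes <- data.frame(name = c(paste(from_name, from_levels),
                               paste(to_name, to_levels)),
                      stringsAsFactors = FALSE)
  links <- expand.grid(source = seq_along(from_levels) - 1L,
                       target = seq_along(to_levels) - 1L)
  links$value <- as.vector(tm$counts)
  links$target <- links$target + length(from_levels)
  links <- links[links$value > 0, , drop = FALSE]
  rownames(links) <- NULL
  list(nodes = nodes, links = links)
}

#' Biomarker screen on the merged intermediate groups
#'
#' Restricts the cohort to patients in the 2020 classifier's intermediate or
#' high-intermediate groups (the two groups whose survival curves overlap)
#' and runs the univariate Cox screen for the requested biomarkers on both
#' endpoints — the analysis that singles out CTNNB1 mutation as the
#' prognostic marker within the merged stratum.
#'
#' @param cohort Cohort data.frame.
#' @param biomarkers Covariate names, see [covariate_codings()].
#' @param labels2020 Optional precomputed 2020 labels aligned with the
#'   cohort.
#' @return List with `rfs` and `os` screen tables (zero-row when the merged
#'   subset is empty) and `n_merged`.
#' @export
merged_intermediate_screen <- function(cohort,
                                       biomarkers = c("er", "pr", "ecad",
                                                      "her2", "arid1a",
                                                      "pten", "l1cam",
                                                      "ctnnb1"),
                                       labels2020 = NULL) {
  if (is.null(labels2020)) labels2020 <- classify_cohort(cohort, "c2020")$label
  stopifnot(length(labels2020) == nrow(cohort))
  sel <- !is.na(labels2020) &
    labels2020 %in% c("intermediate", "high_intermediate")
  sub <- cohort[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    empty <- data.frame(covariate = character(0), n = integer(0),
                        n_events = integer(0), hr = numeric(0),
                        ci_low = numeric(0), ci_high = numeric(0),
                        p_value = numeric(0), coding = character(0),
                        note = character(0), stringsAsFactors = FALSE)
    return(list(rfs = empty, os = empty, n_merged = 0L))
  }
  list(rfs = univariate_screen(sub, biomarkers, "rfs"),
       os = univariate_screen(sub, biomarkers, "os"),
       n_merged = nrow(sub))
}

#' Evaluate the three-tier proposal against the 2020 classifier
#'
#' Builds the 2020 four-group report and the CTNNB1-augmented three-group
#' report on exactly the same patients (those classifiable under both) and
#' returns them side by side with the c-index delta — the comparison behind
#' the proposal. The low groups of the two reports are identical by
#' construction.
#'
#' @param cohort Cohort data.frame.
#' @param endpoint "rfs" or "os".
#' @return List of class `proposal_evaluation`: `report_2020`,
#'   `report_proposal`, `c_index_2020`, `c_index_proposal`, `c_index_delta`,
#'   `n`.
#' @export
evaluate_proposal <- function(cohort, endpoint = c("rfs", "os")) {
  endpoint <- match.arg(endpoint)
  l2020 <- classify_cohort(cohort, "c2020")$label
  lprop <- classify_proposal(
    ifelse(is.na(l2020), "unclassifiable: upstream", l2020),
    cohort$ctnnb1_exon3)
  lprop[is_unclassifiable(lprop)] <- NA
  both <- !is.na(l2020) & !is.na(lprop)
  sub <- cohort[both, , drop = FALSE]
  r2020 <- build_classifier_report(sub, "c2020", endpoint,
                                   labels = l2020[both])
  rprop <- build_classifier_report(sub, "proposal", endpoint,
                                   labels = lprop[both])
  c2020 <- if (!is.null(r2020$concordance)) r2020$concordance$c_index else NA
  cprop <- if (!is.null(rprop$concordance)) rprop$concordance$c_index else NA
  structure(list(report_2020 = r2020, report_proposal = rprop,
                 c_index_2020 = c2020, c_index_proposal = cprop,
                 c_index_delta = cprop - c2020, n = nrow(sub)),
            class = "proposal_evaluation")
}

#' @export
print.proposal_evaluation <- function(x, ...) {
  cat(sprintf("Proposal evaluation on %d patients: c-index %.2f (proposal) vs %.2f (2020), delta %+.3f\n\n",
              x$n, x$c_index_proposal, x$c_index_2020, x$c_index_delta))
  print(x$report_2020); cat("\n"); print(x$report_proposal)
  invisible(x)
}
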