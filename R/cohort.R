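# Patient-level cohort schema, validation and CSV round-trip I/O.
#
# A cohort is a plain data.frame with one row per patient and a fixed column
# set (see cohort_columns()). Categorical columns use a closed vocabulary;
# "NE" (not evaluable) is an explicit missing state for markers that were
# assessed but could not be called, so imputation is always an explicit,
# logged transformation rather than a side effect of NA handling.

#' Canonical cohort column order
#'
#' @return Character vector of the 22 cohort columns in canonical order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", "histology", "grade", "myometrial_invasion",
    "figo_stage", "lvsi", "pole_variant", "mmr_status", "p53_ihc",
    "ctnnb1_exon3", "er", "pr", "ecad", "her2", "arid1a", "pten", "l1cam",
    "rfs_time_months", "rfs_event", "os_time_months", "os_event")
}

#' Closed category vocabularies for the cohort schema
#'
#' @return Named list mapping each categorical column to its allowed tokens.
#'   `pole_variant` is free text (amino-acid change or empty) and is not
#'   listed here.
#' @export
cohort_vocab <- function() {
  marker <- c("positive", "negative", "NE")
  list(
    histology           = c("EEC", "NEEC"),
    grade               = c("G1", "G2", "G3"),
    myometrial_invasion = c("none", "lt50", "ge50"),
    figo_stage          = c("IA", "IB", "II"),
    lvsi                = c("negative", "positive", "NE"),
    mmr_status          = c("deficient", "proficient", "NE"),
    p53_ihc             = c("abnormal", "wildtype", "NE"),
    ctnnb1_exon3        = c("mutated", "wildtype", "NE"),
    er = marker, pr = marker, ecad = marker, her2 = marker,
    arid1a = marker, pten = marker, l1cam = marker
  )
}

numeric_cohort_columns <- function() {
  c("age_years", "rfs_time_months", "os_time_months")
}

event_cohort_columns <- function() {
  c("rfs_event", "os_event")
}

#' Read a cohort CSV
#'
#' Parses a patient-level CSV into a validated cohort data.frame. The header
#' must contain every canonical column (extra columns are rejected to catch
#' schema drift); category tokens outside the closed vocabulary raise a
#' row-level error; empty molecular cells are mapped to the explicit "NE"
#' state ("" in `pole_variant` means wild type and is kept as "").
#'
#' @param path Path to a UTF-8, comma-separated file with a header.
#' @return A cohort data.frame in canonical column order.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file does not exist: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), cohort_columns())
  if (length(extra) > 0) {
    stop("cohort CSV has unknown column(s): ", paste(extra, collapse = ", "))
  }
  df <- df[, cohort_columns(), drop = FALSE]

  vocab <- cohort_vocab()
  for (col in names(vocab)) {
    x <- df[[col]]
    x[is.na(x) | x == ""] <- "NE"
    bad <- which(!x %in% vocab[[col]])
    if (length(bad) > 0) {
      stop(sprintf("invalid token '%s' in column '%s' at data row %d",
                   df[[col]][bad[1]], col, bad[1]))
    }
    df[[col]] <- x
  }
  df$pole_variant[is.na(df$pole_variant)] <- ""

  for (col in numeric_cohort_columns()) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !(is.na(df[[col]]) | df[[col]] == ""))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   df[[col]][bad[1]], col, bad[1]))
    }
    df[[col]] <- val
  }
  for (col in event_cohort_columns()) {
    val <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(!val %in% c(0L, 1L))
    if (length(bad) > 0) {
      stop(sprintf("event column '%s' must be 0/1; offending data row %d",
                   col, bad[1]))
    }
    df[[col]] <- val
  }

  violations <- validate_cohort(df)
  hard <- violations[violations$rule == "duplicate_patient_id", , drop = FALSE]
  if (nrow(hard) > 0) {
    stop("duplicate patient_id: ",
         paste(unique(hard$patient_id), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a cohort CSV
#'
#' Serializes a cohort to the canonical column order, one row per patient,
#' with NE states written literally as "NE" so the file round-trips through
#' [read_cohort()] losslessly.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @return Invisibly, the normalized data.frame that was written.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- cohort[, cohort_columns(), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}

#' Validate a cohort against the schema invariants
#'
#' Reports every invariant violation rather than stopping at the first one:
#' stage/depth inconsistency (FIGO IA requires myometrial invasion none or
#' <50%, IB requires >=50%), RFS time exceeding OS time, non-0/1 event flags,
#' non-positive ages, negative follow-up times, and duplicate patient ids.
#'
#' @param cohort Cohort data.frame.
#' @return A data.frame with columns `patient_id` and `rule`; zero rows iff
#'   the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  v <- list()
  add <- function(ids, rule) {
    if (length(ids) > 0) {
      v[[length(v) + 1]] <<- data.frame(patient_id = as.character(ids),
                                        rule = rule,
                                        stringsAsFactors = FALSE)
    }
  }

  dup <- cohort$patient_id[duplicated(cohort$patient_id)]
  add(unique(dup), "duplicate_patient_id")

  ia_bad <- cohort$figo_stage == "IA" &
    !cohort$myometrial_invasion %in% c("none", "lt50")
  ib_bad <- cohort$figo_stage == "IB" & cohort$myometrial_invasion != "ge50"
  add(cohort$patient_id[which(ia_bad | ib_bad)], "stage_depth_inconsistent")

  ord_bad <- !is.na(cohort$rfs_time_months) & !is.na(cohort$os_time_months) &
    cohort$rfs_time_months > cohort$os_time_months
  add(cohort$patient_id[which(ord_bad)], "rfs_exceeds_os")

  add(cohort$patient_id[which(!is.na(cohort$age_years) &
                                cohort$age_years <= 0)], "nonpositive_age")
  add(cohort$patient_id[which(cohort$rfs_time_months < 0 |
                                cohort$os_time_months < 0)], "negative_time")
  for (col in event_cohort_columns()) {
    add(cohort$patient_id[which(!cohort[[col]] %in% c(0L, 1L))],
        paste0("invalid_", col))
  }

  if (length(v) == 0) {
    return(data.frame(patient_id = character(0), rule = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Derived binary grade
#'
#' The analyses dichotomize differentiation grade as low (G1 or G2) versus
#' high (G3).
#'
#' @param grade Character vector of "G1"/"G2"/"G3".
#' @return Character vector "low"/"high".
#' @export
grade_binary <- function(grade) {
  ifelse(grade == "G3", "high", "low")
}
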