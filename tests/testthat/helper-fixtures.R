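# Shared fixtures and independent oracles.

# One fully specified, schema-valid patient row; override any field.
make_patient <- function(id = "P1", ...) {
  rec <- data.frame(
    patient_id = id, age_years = 62,
    histology = "EEC", grade = "G1", myometrial_invasion = "lt50",
    figo_stage = "IA", lvsi = "negative",
    pole_variant = "", mmr_status = "proficient", p53_ihc = "wildtype",
    ctnnb1_exon3 = "wildtype",
    er = "positive", pr = "positive", ecad = "positive", her2 = "negative",
    arid1a = "negative", pten = "negative", l1cam = "negative",
    rfs_time_months = 60, rfs_event = 0L,
    os_time_months = 60, os_event = 0L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Independent brute-force concordance enumerator: explicit loop over every
# unordered pair, applying the Harrell permissibility rules directly.
brute_force_concordance <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; disc <- 0; tied <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # identify the established-earlier event member, if any
      if (time[i] < time[j]) {
        if (event[i] != 1) next
        short <- i; long <- j
      } else if (time[j] < time[i]) {
        if (event[j] != 1) next
        short <- j; long <- i
      } else {
        if (event[i] + event[j] != 1) next
        if (event[i] == 1) { short <- i; long <- j }
        else { short <- j; long <- i }
      }
      if (scores[short] > scores[long]) conc <- conc + 1
      else if (scores[short] < scores[long]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  perm <- conc + disc + tied
  list(c_index = (conc + 0.5 * tied) / perm,
       concordant = conc, discordant = disc, tied = tied, permissible = perm)
}

# full categorical cross-product over the classifier-relevant vocabulary,
# including NE states and a non-pathogenic POLE token
classifier_grid <- function() {
  expand.grid(
    histology = c("EEC", "NEEC"),
    grade = c("G1", "G2", "G3"),
    myometrial_invasion = c("none", "lt50", "ge50"),
    figo_stage = c("IA", "IB", "II"),
    lvsi = c("negative", "positive", "NE"),
    pole_variant = c("", "P286R", "T278M"),
    mmr_status = c("deficient", "proficient", "NE"),
    p53_ihc = c("abnormal", "wildtype", "NE"),
    ctnnb1_exon3 = c("mutated", "wildtype", "NE"),
    stringsAsFactors = FALSE
  )
}
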