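# The four risk-stratification rule engines, written as pure, total decision
# functions over the cohort vocabulary. Each engine is vectorized over the
# cohort data.frame and returns a character vector of group labels; records
# the rules cannot place (e.g. an LVSI call is needed but NE) get an explicit
# "unclassifiable: <reason>" token, never a silent default. Downstream code
# uses is_unclassifiable() to separate the two.

#' Group labels of each classification scheme
#'
#' @param scheme One of "c2016", "promise", "c2020", "proposal".
#' @return Character vector of group labels in the scheme's canonical
#'   severity order (the ordinal coding used by the Cox fits). For the
#'   risk-group schemes this runs from low to high risk; for ProMisE it is
#'   the classifier's conventional listing POLE, MMRd, NSMP, p53abn.
#' @export
scheme_levels <- function(scheme) {
  switch(match.arg(scheme, c("c2016", "promise", "c2020", "proposal")),
    c2016    = c("low", "intermediate", "high_intermediate", "high"),
    promise  = c("POLE", "MMRd", "NSMP", "p53abn"),
    c2020    = c("low", "intermediate", "high_intermediate", "high"),
    proposal = c("low", "intermediate", "high")
  )
}

#' Test labels for the explicit unclassifiable state
#'
#' @param label Character vector of engine outputs.
#' @return Logical vector, TRUE where the label is an unclassifiable token.
#' @export
is_unclassifiable <- function(label) {
  startsWith(label, "unclassifiable")
}

unclassifiable <- function(reason) paste0("unclassifiable: ", reason)

#' Default pathogenic POLE exonuclease-domain variant whitelist
#'
#' The eleven pathogenic exonuclease-domain (exons 9/13/14) variants used to
#' call the POLE molecular subtype. The list ships as a JSON config file
#' rather than code because it belongs to an external consensus that may be
#' revised; pass a different file to load an updated list.
#'
#' @param path Path to a JSON array of amino-acid-change tokens. Defaults to
#'   the file shipped with the package.
#' @return Character vector of normalized (upper-case) variant tokens.
#' @export
pole_whitelist <- function(path = system.file("extdata", "pole_whitelist.json",
                                              package = "endorisk")) {
  wl <- toupper(trimws(jsonlite::fromJSON(path)))
  if (length(wl) == 0) stop("POLE whitelist must be non-empty")
  wl
}

#' Is a POLE variant call pathogenic?
#'
#' Membership test against the pathogenic-variant whitelist; matching is
#' case-insensitive on the trimmed token. An empty string (wild type) is
#' never pathogenic; exonuclease-domain alterations outside the whitelist are
#' not used for classification.
#'
#' @param variant Character vector of amino-acid-change tokens ("" = none).
#' @param whitelist Character vector from [pole_whitelist()].
#' @return Logical vector.
#' @export
is_pole_pathogenic <- function(variant, whitelist = pole_whitelist()) {
  if (length(whitelist) == 0) stop("POLE whitelist must be non-empty")
  norm <- toupper(trimws(variant))
  !is.na(norm) & norm != "" & norm %in% toupper(trimws(whitelist))
}

#' ESMO-ESGO-ESTRO 2016 clinicopathological classifier
#'
#' Four-group risk stratification from histology, grade, FIGO stage and LVSI
#' (stage I-II domain): low = stage IA endometrioid G1-G2 LVSI-negative;
#' intermediate = stage IB endometrioid G1-G2 LVSI-negative;
#' high-intermediate = stage IA endometrioid G3 (any LVSI) or stage I
#' endometrioid G1-G2 LVSI-positive; high = stage IB endometrioid G3,
#' stage II, or any non-endometrioid histology.
#'
#' @param cohort Cohort data.frame (only the clinicopathological columns are
#'   used).
#' @return Character vector of labels in `scheme_levels("c2016")`, or
#'   "unclassifiable: missing LVSI" where the rule needs an NE LVSI call.
#' @export
classify_2016 <- function(cohort) {
  n <- nrow(cohort)
  out <- character(n)
  hist <- cohort$histology
  grd <- grade_binary(cohort$grade)
  stg <- cohort$figo_stage
  lvsi <- cohort$lvsi
  for (i in seq_len(n)) {
    out[i] <-
      if (hist[i] == "NEEC") "high"
      else if (stg[i] == "II") "high"
      else if (grd[i] == "high") {
        if (stg[i] == "IB") "high" else "high_intermediate"
      } else if (lvsi[i] == "positive") "high_intermediate"
      else if (lvsi[i] == "NE") unclassifiable("missing LVSI")
      else if (stg[i] == "IA") "low"
      else "intermediate"
  }
  out
}

#' ProMisE molecular subtype
#'
#' Assigns POLE / MMRd / p53abn / NSMP from the surrogate markers with the
#' precedence POLE -> MMRd -> p53abn -> NSMP: a pathogenic POLE variant
#' dominates every other call, mismatch-repair deficiency dominates aberrant
#' p53, and NSMP is the residual class. Outside the POLE branch an NE marker
#' that could change the call (NE MMR anywhere; NE p53 in an MMR-proficient
#' tumour) yields an unclassifiable outcome for the caller to impute.
#'
#' @param cohort Cohort data.frame.
#' @param whitelist Pathogenic POLE variant tokens, see [pole_whitelist()].
#' @return Character vector over `scheme_levels("promise")` plus
#'   unclassifiable tokens.
#' @export
assign_molecular_subtype <- function(cohort, whitelist = pole_whitelist()) {
  pole <- is_pole_pathogenic(cohort$pole_variant, whitelist)
  mmr <- cohort$mmr_status
  p53 <- cohort$p53_ihc
  out <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    out[i] <-
      if (pole[i]) "POLE"
      else if (mmr[i] == "deficient") "MMRd"
      else if (mmr[i] == "NE") {
        if (p53[i] == "NE") unclassifiable("missing molecular data")
        else unclassifiable("missing MMR status")
      }
      else if (p53[i] == "abnormal") "p53abn"
      else if (p53[i] == "NE") unclassifiable("missing p53 IHC")
      else "NSMP"
  }
  out
}

#' ESGO-ESTRO-ESP 2020 molecular-integrated classifier
#'
#' Four-group stratification combining the ProMisE subtype with the
#' clinicopathological variables (stage I-II domain): stage I-II POLE-mutated
#' tumours are low risk; p53abn (or non-endometrioid) tumours are high risk
#' when myometrial invasion is present and intermediate without invasion;
#' MMRd/NSMP endometrioid tumours follow stage, binary grade and LVSI:
#' stage IA low-grade LVSI-negative = low; stage IB low-grade LVSI-negative
#' or stage IA high-grade LVSI-negative = intermediate; LVSI-positive stage I
#' (any grade or depth), stage IB high-grade, or stage II =
#' high-intermediate. Binary LVSI positivity is mapped onto the guideline's
#' substantial-LVSI branch.
#'
#' @param cohort Cohort data.frame.
#' @param subtype Molecular subtype labels, usually from
#'   [assign_molecular_subtype()]; unclassifiable subtypes propagate.
#' @return Character vector over `scheme_levels("c2020")` plus
#'   unclassifiable tokens.
#' @export
classify_2020 <- function(cohort, subtype = assign_molecular_subtype(cohort)) {
  stopifnot(length(subtype) == nrow(cohort))
  hist <- cohort$histology
  grd <- grade_binary(cohort$grade)
  stg <- cohort$figo_stage
  lvsi <- cohort$lvsi
  inv <- cohort$myometrial_invasion != "none"
  out <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    out[i] <-
      if (is_unclassifiable(subtype[i])) subtype[i]
      else if (subtype[i] == "POLE") "low"
      else if (subtype[i] == "p53abn" || hist[i] == "NEEC") {
        if (inv[i]) "high" else "intermediate"
      }
      else if (stg[i] == "II") "high_intermediate"
      else if (stg[i] == "IB" && grd[i] == "high") "high_intermediate"
      else if (lvsi[i] == "positive") "high_intermediate"
      else if (lvsi[i] == "NE") unclassifiable("missing LVSI")
      else if (stg[i] == "IA" && grd[i] == "low") "low"
      else "intermediate"
  }
  out
}

#' CTNNB1-augmented three-tier stratification
#'
#' Collapses the 2020 classifier to three groups using CTNNB1 exon-3 status:
#' the low and high groups pass through unchanged; the two intermediate
#' groups merge, with CTNNB1-mutated cases reallocated to the high-risk group
#' and CTNNB1 wild-type cases forming the redefined intermediate group. An NE
#' CTNNB1 call (surviving imputation) is treated as wild type — a
#' conservative default given the low mutation prevalence.
#'
#' @param group2020 Labels from [classify_2020()]; unclassifiable tokens
#'   propagate.
#' @param ctnnb1 Character vector over mutated/wildtype/NE.
#' @return Character vector over `scheme_levels("proposal")` plus propagated
#'   unclassifiable tokens.
#' @export
classify_proposal <- function(group2020, ctnnb1) {
  stopifnot(length(group2020) == length(ctnnb1),
            all(ctnnb1 %in% c("mutated", "wildtype", "NE")))
  ifelse(is_unclassifiable(group2020), group2020,
  ifelse(group2020 == "low", "low",
  ifelse(group2020 == "high", "high",
  ifelse(ctnnb1 == "mutated", "high", "intermediate"))))
}

#' Classify every patient of a cohort under one scheme
#'
#' Thin composition over the per-scheme engines returning a per-patient label
#' table; unclassifiable outcomes are surfaced in a `reason` column, never
#' dropped.
#'
#' @param cohort Cohort data.frame.
#' @param scheme One of "c2016", "promise", "c2020", "proposal".
#' @param whitelist Pathogenic POLE whitelist for the molecular schemes.
#' @return data.frame with columns `patient_id`, `label` (NA when
#'   unclassifiable) and `reason` (NA when classified).
#' @export
classify_cohort <- function(cohort, scheme, whitelist = pole_whitelist()) {
  scheme <- match.arg(scheme, c("c2016", "promise", "c2020", "proposal"))
  raw <- switch(scheme,
    c2016 = classify_2016(cohort),
    promise = assign_molecular_subtype(cohort, whitelist),
    c2020 = classify_2020(cohort, assign_molecular_subtype(cohort, whitelist)),
    proposal = classify_proposal(
      classify_2020(cohort, assign_molecular_subtype(cohort, whitelist)),
      cohort$ctnnb1_exon3)
  )
  un <- is_unclassifiable(raw)
  data.frame(
    patient_id = as.character(cohort$patient_id),
    label = ifelse(un, NA_character_, raw),
    reason = ifelse(un, sub("^unclassifiable: ", "", raw), NA_character_),
    stringsAsFactors = FALSE
  )
}
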