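test_that("2016 classifier reproduces the rule table", {
  cases <- list(
    list(make_patient("a", grade = "G1", figo_stage = "IA",
                      myometrial_invasion = "lt50"), "low"),
    list(make_patient("b", grade = "G2", figo_stage = "IB",
                      myometrial_invasion = "ge50"), "intermediate"),
    list(make_patient("c", grade = "G1", figo_stage = "IA",
                      myometrial_invasion = "lt50", lvsi = "positive"),
         "high_intermediate"),
    list(make_patient("d", grade = "G3", figo_stage = "IA"),
         "high_intermediate"),
    list(make_patient("e", grade = "G3", figo_stage = "IB",
                      myometrial_invasion = "ge50"), "high"),
    list(make_patient("f", histology = "NEEC", grade = "G3"), "high"),
    list(make_patient("g", figo_stage = "II"), "high")
  )
  for (cs in cases) {
    expect_identical(classify_2016(cs[[1]]), cs[[2]],
                     label = paste("record", cs[[1]]$patient_id))
  }
  # LVSI is needed on the low/intermediate branches
  expect_identical(classify_2016(make_patient("h", lvsi = "NE")),
                   "unclassifiable: missing LVSI")
  # ...but not where grade or histology already decides
  expect_identical(classify_2016(make_patient("i", grade = "G3",
                                              lvsi = "NE")),
                   "high_intermediate")
})

test_that("POLE pathogenicity is a case-insensitive whitelist test", {
  expect_true(is_pole_pathogenic("P286R"))
  expect_true(is_pole_pathogenic("p286r"))
  expect_true(is_pole_pathogenic(" V411L "))
  expect_false(is_pole_pathogenic(""))
  # exonuclease-domain alteration outside the pathogenic list is ignored
  expect_false(is_pole_pathogenic("T278M"))
  expect_equal(length(pole_whitelist()), 11)
  expect_true(is_pole_pathogenic("Q99X", whitelist = c("Q99X")))
  expect_error(is_pole_pathogenic("P286R", whitelist = character(0)),
               "non-empty")
})

test_that("molecular subtype follows the POLE > MMRd > p53abn > NSMP precedence", {
  expect_identical(
    assign_molecular_subtype(make_patient("a", pole_variant = "V411L",
                                          mmr_status = "deficient",
                                          p53_ihc = "abnormal")), "POLE")
  expect_identical(
    assign_molecular_subtype(make_patient("b", mmr_status = "deficient",
                                          p53_ihc = "abnormal")), "MMRd")
  expect_identical(
    assign_molecular_subtype(make_patient("c", p53_ihc = "abnormal")),
    "p53abn")
  expect_identical(assign_molecular_subtype(make_patient("d")), "NSMP")
  # a non-pathogenic EDM variant does not trigger the POLE branch
  expect_identical(
    assign_molecular_subtype(make_patient("e", pole_variant = "T278M",
                                          mmr_status = "deficient")), "MMRd")
  # NE markers that could change the call are unclassifiable
  expect_match(assign_molecular_subtype(make_patient("f",
                                                     mmr_status = "NE")),
               "^unclassifiable")
  expect_match(assign_molecular_subtype(make_patient("g", p53_ihc = "NE")),
               "^unclassifiable")
  expect_identical(
    assign_molecular_subtype(make_patient("h", mmr_status = "NE",
                                          p53_ihc = "NE")),
    "unclassifiable: missing molecular data")
})

test_that("2020 classifier integrates subtype with the clinicopathological rules", {
  g2020 <- function(p) classify_2020(p, assign_molecular_subtype(p))
  expect_identical(g2020(make_patient("a")), "low")
  # POLE dominates adverse clinicopathology
  expect_identical(g2020(make_patient("b", pole_variant = "P286R",
                                      grade = "G3", figo_stage = "IB",
                                      myometrial_invasion = "ge50")), "low")
  # p53abn with any myometrial invasion is high...
  expect_identical(g2020(make_patient("c", p53_ihc = "abnormal")), "high")
  # ...but intermediate without invasion
  expect_identical(g2020(make_patient("d", p53_ihc = "abnormal",
                                      myometrial_invasion = "none")),
                   "intermediate")
  expect_identical(g2020(make_patient("e", histology = "NEEC", grade = "G3",
                                      myometrial_invasion = "none")),
                   "intermediate")
  expect_identical(g2020(make_patient("f", figo_stage = "IB",
                                      myometrial_invasion = "ge50")),
                   "intermediate")
  expect_identical(g2020(make_patient("g", grade = "G3")), "intermediate")
  expect_identical(g2020(make_patient("h", lvsi = "positive")),
                   "high_intermediate")
  expect_identical(g2020(make_patient("i", figo_stage = "II")),
                   "high_intermediate")
  expect_identical(g2020(make_patient("j", grade = "G3", figo_stage = "IB",
                                      myometrial_invasion = "ge50")),
                   "high_intermediate")
  expect_identical(g2020(make_patient("k", lvsi = "NE")),
                   "unclassifiable: missing LVSI")
})

test_that("three-tier proposal merges intermediates by CTNNB1 status", {
  expect_identical(classify_proposal("low", "mutated"), "low")
  expect_identical(classify_proposal("high", "wildtype"), "high")
  expect_identical(classify_proposal("intermediate", "wildtype"),
                   "intermediate")
  expect_identical(classify_proposal("intermediate", "mutated"), "high")
  expect_identical(classify_proposal("high_intermediate", "mutated"), "high")
  expect_identical(classify_proposal("high_intermediate", "NE"),
                   "intermediate")
  expect_match(classify_proposal("unclassifiable: missing LVSI", "mutated"),
               "^unclassifiable")
})

test_that("switching CTNNB1 to mutated never lowers the proposal label", {
  sev <- function(x) match(x, scheme_levels("proposal"))
  for (g in scheme_levels("c2020")) {
    expect_gte(sev(classify_proposal(g, "mutated")),
               sev(classify_proposal(g, "wildtype")))
  }
})

test_that("proposal low equals 2020 low and proposal high contains 2020 high", {
  cfg <- sim_config(n_patients = 400, group_scheme = "c2020",
                    missingness = NULL, seed = 42)
  coh <- generate_cohort(cfg)
  l2020 <- classify_cohort(coh, "c2020")$label
  lprop <- classify_cohort(coh, "proposal")$label
  expect_false(anyNA(l2020))
  expect_identical(which(lprop == "low"), which(l2020 == "low"))
  expect_true(all(which(l2020 == "high") %in% which(lprop == "high")))
})

test_that("classify_cohort composes the engines and surfaces unclassifiables", {
  coh <- make_cohort(
    make_patient("a"),
    make_patient("b", lvsi = "NE"),
    make_patient("c", p53_ihc = "abnormal")
  )
  t16 <- classify_cohort(coh, "c2016")
  expect_identical(t16$label, c("low", NA, "low"))
  expect_identical(t16$reason, c(NA, "missing LVSI", NA))
  t20 <- classify_cohort(coh, "c2020")
  expect_identical(t20$label, c("low", NA, "high"))

  empty <- classify_cohort(make_patient("x")[0, ], "promise")
  expect_equal(nrow(empty), 0)
})

test_that("subtype assignment is invariant to non-dominant marker values", {
  # once the dominant marker fires, every combination of the others gives
  # the same subtype
  for (mmr in c("deficient", "proficient", "NE")) {
    for (p53 in c("abnormal", "wildtype", "NE")) {
      expect_identical(
        assign_molecular_subtype(make_patient("x", pole_variant = "S297F",
                                              mmr_status = mmr,
                                              p53_ihc = p53)), "POLE")
      expect_identical(
        assign_molecular_subtype(make_patient("y", mmr_status = "deficient",
                                              p53_ihc = p53)), "MMRd")
    }
  }
})
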