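test_that("product-limit estimate matches the hand computation", {
  km <- km_estimate(c(10, 20, 30), c(1, 1, 1))
  expect_equal(km$event_times, c(10, 20, 30))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))
  # Greenwood: var S(10) = S^2 * d/(n(n-d)) = (2/3)^2 * 1/(3*2)
  expect_equal(km$greenwood_var[1], (2 / 3)^2 * (1 / 6))
  expect_equal(km$greenwood_var[2], (1 / 3)^2 * (1 / 6 + 1 / 2))

  # censoring tied with an event is processed after the event
  km2 <- km_estimate(c(10, 10, 20), c(1, 0, 1))
  expect_equal(km2$survival, c(2 / 3, 0))
})

test_that("all-censored data gives S(t) = 1 and step lookup works", {
  km <- km_estimate(rep(c(5, 15, 25), c(4, 3, 3)), rep(0, 10))
  expect_length(km$event_times, 0)
  expect_equal(survival_at(km, 20), 1)

  km3 <- km_estimate(c(10, 20, 30), c(1, 1, 1))
  expect_equal(survival_at(km3, 0), 1)
  expect_equal(survival_at(km3, 25), 1 / 3)
  expect_equal(survival_at(km3, 10), 2 / 3)
  expect_warning(out <- survival_at(km3, 31), "beyond the last observed")
  expect_equal(out, 0)
  expect_error(survival_at(km3, -1), "non-negative")
  expect_error(km_estimate(c(0, 0), c(1, 1)), "zero")
})

test_that("no-censoring KM equals the empirical survival function exactly", {
  set.seed(21)
  for (rep in 1:20) {
    t <- round(rexp(50, 0.02), 1) + 0.1
    km <- km_estimate(t, rep(1, 50))
    for (tt in c(10, 35.5, 80)) {
      expect_equal(suppressWarnings(survival_at(km, tt)), mean(t > tt))
    }
  }
})

test_that("KM S(60) recovers the truth of a large exponential simulation", {
  set.seed(31)
  lam <- calibrate_hazard(0.5)
  t <- rexp(10000, lam)
  cens <- censoring_times(10000)
  km <- km_estimate(pmin(t, cens), as.integer(t <= cens))
  expect_equal(survival_at(km, 60), 0.5, tolerance = 0.04)
})

test_that("Cox fit recovers null and true hazard ratios and flags degeneracy", {
  set.seed(41)
  # null: two groups with identical exponential hazard
  x <- rep(0:1, each = 1000)
  t <- rexp(2000, 0.02)
  f0 <- cox_fit(t, rep(1, 2000), x)
  expect_lt(abs(f0$beta), 3 * f0$se)

  # true HR 2, no censoring
  t2 <- rexp(2000, 0.02 * ifelse(x == 1, 2, 1))
  f2 <- cox_fit(t2, rep(1, 2000), x)
  expect_lt(abs(f2$beta - log(2)), 3 * f2$se)
  expect_gt(f2$ci95[["high"]], f2$hr)
  expect_lt(f2$ci95[["low"]], f2$hr)
  expect_true(f2$converged)

  expect_error(cox_fit(t2, rep(1, 2000), rep(1, 2000)), "constant")
  expect_error(cox_fit(c(5, 10), c(0, 0), c(0, 1)), "no events")

  # monotone likelihood (perfect separation) is flagged, not silent
  sep <- cox_fit(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
                 c(1, 1, 1, 0, 0, 0))
  expect_false(sep$converged)
})

test_that("Efron and Breslow tie handling are both available and recorded", {
  set.seed(43)
  t <- sample(1:8, 60, replace = TRUE)
  x <- rnorm(60)
  fe <- cox_fit(t, rep(1, 60), x, ties = "efron")
  fb <- cox_fit(t, rep(1, 60), x, ties = "breslow")
  expect_identical(fe$ties, "efron")
  expect_identical(fb$ties, "breslow")
  expect_false(isTRUE(all.equal(fe$beta, fb$beta)))
})

test_that("ordinal group fit estimates the per-step hazard ratio", {
  set.seed(47)
  g <- sample(c("low", "mid", "high"), 3000, replace = TRUE)
  step <- match(g, c("low", "mid", "high"))
  t <- rexp(3000, 0.01 * 2.5^(step - 1))
  fit <- cox_ordinal_by_group(g, t, rep(1, 3000),
                              levels = c("low", "mid", "high"))
  expect_lt(abs(fit$beta - log(2.5)), 3 * fit$se)
  expect_match(fit$covariate_coding, "low=1, mid=2, high=3")
  expect_gt(fit$beta, 0)

  # equal hazards across 4 groups: HR ~ 1
  g4 <- sample(letters[1:4], 4000, replace = TRUE)
  t4 <- rexp(4000, 0.02)
  f4 <- cox_ordinal_by_group(g4, t4, rep(1, 4000), levels = letters[1:4])
  expect_lt(abs(f4$beta), 3 * f4$se)

  expect_error(cox_ordinal_by_group(rep("a", 10), rexp(10), rep(1, 10)),
               ">= 2 distinct groups")
})

test_that("concordance matches the worked example and its exposed counts", {
  # 6 pairs enumerated by hand: times (2,4,6,8), events (1,1,0,1),
  # scores (4,3,2,1): permissible pairs (1,2),(1,3),(1,4),(2,3),(2,4),(4,3*)
  # -> (2,4)... pair (3,4): t=6 censored before t=8 event -> not permissible
  res <- concordance_index(c(4, 3, 2, 1), c(2, 4, 6, 8), c(1, 1, 0, 1))
  oracle <- brute_force_concordance(c(4, 3, 2, 1), c(2, 4, 6, 8),
                                    c(1, 1, 0, 1))
  expect_equal(res$c_index, oracle$c_index)
  expect_equal(res$permissible, 5)
  expect_equal(res$concordant, 5)
  expect_equal(res$c_index, 1)
  expect_equal(res$concordant + res$discordant + res$tied, res$permissible)
})

test_that("concordance handles perfect, random-tie and undefined cases", {
  # all events, scores perfectly anti-ordered with times
  expect_equal(concordance_index(5:1, 1:5, rep(1, 5))$c_index, 1)
  # constant scores: all permissible pairs tie -> 0.5
  expect_equal(concordance_index(rep(2, 6), 1:6, rep(1, 6))$c_index, 0.5)
  # no permissible pairs
  expect_error(concordance_index(1:3, c(5, 6, 7), c(0, 0, 0)),
               "no permissible pairs")
})

test_that("concordance is rank-invariant and sign-reversible", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    sc <- rnorm(n)
    t <- rexp(n, 0.1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    base <- concordance_index(sc, t, ev)
    expect_equal(concordance_index(exp(2 * sc) + 5, t, ev)$c_index,
                 base$c_index)
    expect_equal(concordance_index(-sc, t, ev)$c_index, 1 - base$c_index)
  }
})

test_that("concordance agrees with the survival package on censored data", {
  set.seed(59)
  t <- rexp(200, 0.02)
  cens <- runif(200, 0, 100)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  sc <- -t + rnorm(200, sd = 20)  # noisy risk score, no exact ties
  ours <- concordance_index(sc, time, ev)
  ref <- survival::concordance(survival::Surv(time, ev) ~ sc, reverse = TRUE)
  expect_equal(ours$c_index, unname(ref$concordance), tolerance = 1e-10)
})

test_that("log-rank test satisfies its contract cases", {
  t <- rexp(40, 0.05)
  # two identical groups by duplication: statistic 0
  lr0 <- logrank_test(rep(c("a", "b"), each = 40), c(t, t),
                      rep(1, 80))
  expect_equal(lr0$chisq, 0, tolerance = 1e-10)
  expect_equal(lr0$df, 1)

  lr3 <- logrank_test(sample(c("a", "b", "c"), 60, replace = TRUE),
                      rexp(60, 0.05), rep(1, 60))
  expect_equal(lr3$df, 2)
  expect_error(logrank_test(rep("a", 10), rexp(10), rep(1, 10)),
               ">= 2 groups")
})

test_that("log-rank detects a hazard ratio of 3 with high power", {
  set.seed(61)
  hits <- 0
  for (r in 1:60) {
    x <- rep(0:1, each = 150)
    t <- rexp(300, 0.01 * ifelse(x == 1, 3, 1))
    cens <- censoring_times(300)
    lr <- logrank_test(x, pmin(t, cens), as.integer(t <= cens))
    hits <- hits + (lr$p_value < 0.05)
  }
  expect_gte(hits / 60, 0.95)
})

test_that("univariate screen recovers a protective marker effect", {
  set.seed(67)
  n <- 2000
  coh <- do.call(rbind, lapply(seq_len(n), function(i) make_patient(paste0("P", i))))
  coh$er <- sample(c("positive", "negative"), n, replace = TRUE)
  t <- rexp(n, 0.02 * ifelse(coh$er == "positive", 0.4, 1))
  cens <- censoring_times(n)
  coh$rfs_time_months <- pmin(t, cens)
  coh$rfs_event <- as.integer(t <= cens)
  coh$os_time_months <- coh$rfs_time_months
  coh$os_event <- coh$rfs_event

  scr <- univariate_screen(coh, c("er", "pten"), "rfs")
  er_row <- scr[scr$covariate == "er", ]
  expect_equal(er_row$hr, 0.4, tolerance = 0.15)
  expect_lt(er_row$ci_low, 0.4 + 0.15)
  expect_identical(er_row$note, "ok")
})

test_that("degenerate covariates get a no-fit entry, not numbers", {
  coh <- make_cohort(make_patient("a", rfs_event = 1L),
                     make_patient("b"), make_patient("c"))
  scr <- univariate_screen(coh, c("er", "ctnnb1"), "rfs")
  expect_true(all(is.na(scr$hr)))
  expect_match(scr$note[scr$covariate == "er"], "constant")
  expect_error(univariate_screen(coh, "nosuch", "rfs"), "unknown covariate")
})
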