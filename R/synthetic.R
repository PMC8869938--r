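# Synthetic-cohort generator calibrated to the published cohort statistics:
# group proportions and five-year relapse-free survival rates per classifier,
# clinicopathological and biomarker marginal frequencies, and a censoring
# model targeting the 75-month median follow-up (uniform accrual over 144
# months with an administrative horizon of 147 months, so censoring times
# are uniform on [3, 147]).
#
# In group_anchored mode each patient first draws a risk-group label and an
# exponential event time calibrated to that group's five-year rate, then a
# feature bundle that the corresponding rule engine maps back to exactly the
# anchored group (sampled among all consistent bundles with weights from the
# marginal frequencies), so classification round-trips by construction. In
# marginal mode features are drawn from the marginals with a minimal
# dependency structure (molecular subtype linked to histology and grade;
# stage linked to invasion depth) and labels are derived by the engines.

sim_group_tables <- function() {
  list(
    c2016 = list(proportions = c(147, 42, 51, 53) / 293,
                 five_year_rfs = c(0.932, 0.769, 0.775, 0.504)),
    promise = list(proportions = c(5, 68, 186, 34) / 293,
                   five_year_rfs = c(1.00, 0.747, 0.873, 0.528)),
    c2020 = list(proportions = c(145, 60, 50, 38) / 293,
                 five_year_rfs = c(0.939, 0.795, 0.722, 0.415)),
    proposal = list(proportions = c(145, 100, 48) / 293,
                    five_year_rfs = c(0.939, 0.791, 0.427))
  )
}

sim_feature_marginals <- function() {
  list(
    histology_eec = 0.884,
    grade = c(G1 = 0.50, G2 = 0.302, G3 = 0.198),
    stage_invasion = c("IA.none" = 0.198, "IA.lt50" = 0.495,
                       "IB.ge50" = 0.249, "II.none" = 0.000,
                       "II.lt50" = 0.029, "II.ge50" = 0.029),
    lvsi_positive = 0.18,
    pole_pathogenic = 5 / 293,
    pole_nonpathogenic_edm = 7 / 293,
    mmr_deficient = 68 / 293,
    p53_abnormal = 34 / 293,
    ctnnb1_mutated = 23 / 272,
    er_positive = 244 / 283, pr_positive = 235 / 279,
    ecad_positive = 234 / 280, her2_positive = 3 / 292,
    arid1a_positive = 61 / 280, pten_positive = 94 / 287,
    l1cam_positive = 32 / 279
  )
}

sim_missingness_defaults <- function() {
  c(lvsi = 2 / 293, ctnnb1_exon3 = 21 / 293, mmr_status = 0.02,
    p53_ihc = 0.02, er = 10 / 293, pr = 14 / 293, ecad = 13 / 293,
    her2 = 1 / 293, arid1a = 13 / 293, pten = 6 / 293, l1cam = 14 / 293)
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the published cohort conditions: n = 293 patients,
#' per-classifier group proportions and five-year RFS rates, marginal
#' feature frequencies, NE missingness rates, and a censoring model whose
#' median follow-up is 75 months.
#'
#' @param n_patients Cohort size.
#' @param mode "group_anchored" (labels drawn first, features consistent by
#'   construction) or "marginal" (features drawn, labels derived).
#' @param group_scheme Scheme whose groups anchor the survival model.
#' @param group_proportions Probability vector over
#'   `scheme_levels(group_scheme)`.
#' @param five_year_rfs Per-group S(60) values in (0, 1].
#' @param feature_marginals Named list of marginal frequencies (see
#'   defaults).
#' @param missingness Named per-column NE probabilities; set to `NULL` or an
#'   empty vector for complete data.
#' @param accrual_months,horizon_months Censoring model: accrual uniform
#'   over `accrual_months`, administrative cutoff at `horizon_months`, so
#'   censoring ~ U(horizon - accrual, horizon).
#' @param post_relapse_median_months Median of the exponential post-relapse
#'   survival used to build disease-specific OS (only relapsing patients can
#'   die of disease).
#' @param weibull_shape Shape of the event-time distribution; 1 =
#'   exponential (the default calibration), other values for sensitivity
#'   checks (scale re-solved so S(60) still equals the configured rate).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 293,
                       mode = c("group_anchored", "marginal"),
                       group_scheme = c("c2020", "c2016", "promise",
                                        "proposal"),
                       group_proportions = NULL,
                       five_year_rfs = NULL,
                       feature_marginals = sim_feature_marginals(),
                       missingness = sim_missingness_defaults(),
                       accrual_months = 144, horizon_months = 147,
                       post_relapse_median_months = 24,
                       weibull_shape = 1, seed = 1L) {
  mode <- match.arg(mode)
  group_scheme <- match.arg(group_scheme)
  defaults <- sim_group_tables()[[group_scheme]]
  if (is.null(group_proportions)) group_proportions <- defaults$proportions
  if (is.null(five_year_rfs)) five_year_rfs <- defaults$five_year_rfs
  lev <- scheme_levels(group_scheme)
  stopifnot(n_patients >= 1,
            length(group_proportions) == length(lev),
            length(five_year_rfs) == length(lev),
            abs(sum(group_proportions) - 1) < 1e-9,
            all(five_year_rfs > 0 & five_year_rfs <= 1),
            horizon_months > accrual_months, weibull_shape > 0)
  structure(list(n_patients = as.integer(n_patients), mode = mode,
                 group_scheme = group_scheme,
                 group_proportions = stats::setNames(group_proportions, lev),
                 five_year_rfs = stats::setNames(five_year_rfs, lev),
                 feature_marginals = feature_marginals,
                 missingness = missingness,
                 accrual_months = accrual_months,
                 horizon_months = horizon_months,
                 post_relapse_median_months = post_relapse_median_months,
                 weibull_shape = weibull_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Monthly exponential hazard from a five-year survival rate
#'
#' Closed-form calibration lambda = -ln(S60)/60, so the exponential model
#' reproduces the five-year rate exactly: S(60) = exp(-60 lambda) = S60.
#'
#' @param five_year_rate Survival probability at 60 months, in (0, 1].
#' @return Monthly hazard rate (0 when the rate is 1).
#' @export
calibrate_hazard <- function(five_year_rate) {
  if (any(five_year_rate <= 0 | five_year_rate > 1)) {
    stop("five-year rate must be in (0, 1]")
  }
  -log(five_year_rate) / 60
}

#' Censoring times of the accrual/administrative-cutoff model
#'
#' @param n Number of draws.
#' @param config A [sim_config()] (only the accrual and horizon fields are
#'   used).
#' @return Censoring times, uniform on (horizon - accrual, horizon) months.
#' @export
censoring_times <- function(n, config = sim_config()) {
  stats::runif(n, config$horizon_months - config$accrual_months,
               config$horizon_months)
}

# event times with S(60) = rate under the configured shape (shape 1 =
# exponential); rate 1 means no events (infinite times)
sim_event_times <- function(n, five_year_rate, shape = 1) {
  if (five_year_rate >= 1) return(rep(Inf, n))
  scale <- 60 / (-log(five_year_rate))^(1 / shape)
  stats::rweibull(n, shape = shape, scale = scale)
}

# Exhaustive enumeration of classifier-relevant feature bundles with their
# labels under all four schemes and their marginal sampling weight.
# stage/depth pairs are restricted to the schema-consistent combinations.
bundle_table <- local({
  cache <- NULL
  function(marginals = sim_feature_marginals()) {
    key <- digest_marginals(marginals)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    si <- names(marginals$stage_invasion)
    grid <- expand.grid(
      histology = c("EEC", "NEEC"),
      grade = c("G1", "G2", "G3"),
      stage_invasion = si,
      lvsi = c("negative", "positive"),
      pole = c("none", "pathogenic"),
      mmr_status = c("proficient", "deficient"),
      p53_ihc = c("wildtype", "abnormal"),
      ctnnb1_exon3 = c("wildtype", "mutated"),
      stringsAsFactors = FALSE
    )
    grid$figo_stage <- sub("\\..*$", "", grid$stage_invasion)
    grid$myometrial_invasion <- sub("^.*\\.", "", grid$stage_invasion)
    grid$pole_variant <- ifelse(grid$pole == "pathogenic", "P286R", "")

    m <- marginals
    p_of <- function(p, yes) ifelse(yes, p, 1 - p)
    grid$weight <-
      p_of(m$histology_eec, grid$histology == "EEC") *
      m$grade[grid$grade] *
      m$stage_invasion[grid$stage_invasion] *
      p_of(m$lvsi_positive, grid$lvsi == "positive") *
      p_of(m$pole_pathogenic, grid$pole == "pathogenic") *
      p_of(m$mmr_deficient, grid$mmr_status == "deficient") *
      p_of(m$p53_abnormal, grid$p53_ihc == "abnormal") *
      p_of(m$ctnnb1_mutated, grid$ctnnb1_exon3 == "mutated")

    subtype <- assign_molecular_subtype(grid)
    g2020 <- classify_2020(grid, subtype)
    grid$label_c2016 <- classify_2016(grid)
    grid$label_promise <- subtype
    grid$label_c2020 <- g2020
    grid$label_proposal <- classify_proposal(g2020, grid$ctnnb1_exon3)
    attr(grid, "key") <- key
    cache <<- grid
    grid
  }
})

digest_marginals <- function(m) {
  paste(unlist(m), collapse = "|")
}

#' Sample feature bundles consistent with a risk group
#'
#' Inverse of the classifier rule tables: returns clinicopathological and
#' molecular field combinations that the scheme's engine maps back to
#' exactly the requested group, sampled among all consistent bundles with
#' weights given by the marginal feature frequencies. Pathogenic POLE
#' bundles get a whitelist token drawn uniformly; a fraction of wild-type
#' bundles carry a non-pathogenic exonuclease-domain token (which the
#' engines ignore).
#'
#' @param group Group label, valid for `scheme`.
#' @param scheme One of "c2016", "promise", "c2020", "proposal".
#' @param n Number of bundles to draw.
#' @param marginals Marginal frequency list, see [sim_feature_marginals()].
#' @return data.frame of `n` partial patient records (classifier fields
#'   only).
#' @export
feature_bundle_for_group <- function(group, scheme, n = 1,
                                     marginals = sim_feature_marginals()) {
  scheme <- match.arg(scheme, c("c2016", "promise", "c2020", "proposal"))
  if (!group %in% scheme_levels(scheme)) {
    stop(sprintf("'%s' is not a %s group", group, scheme))
  }
  tab <- bundle_table(marginals)
  rows <- tab[tab[[paste0("label_", scheme)]] == group & tab$weight > 0, ,
              drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no feasible feature bundle for %s group '%s' under the configured marginals",
                 scheme, group))
  }
  picked <- rows[sample(nrow(rows), n, replace = TRUE,
                        prob = rows$weight), , drop = FALSE]
  wl <- pole_whitelist()
  path <- picked$pole == "pathogenic"
  picked$pole_variant[path] <- sample(wl, sum(path), replace = TRUE)
  # non-pathogenic exonuclease-domain alterations, ignored by the engines
  nonpath_rate <- marginals$pole_nonpathogenic_edm /
    max(1 - marginals$pole_pathogenic, 1e-12)
  edm <- !path & stats::runif(nrow(picked)) < nonpath_rate
  picked$pole_variant[edm] <- sample(c("T278M", "N363K", "A465V"),
                                     sum(edm), replace = TRUE)
  cols <- c("histology", "grade", "myometrial_invasion", "figo_stage",
            "lvsi", "pole_variant", "mmr_status", "p53_ihc", "ctnnb1_exon3")
  out <- picked[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

sim_biomarkers <- function(n, marginals) {
  draw <- function(p) ifelse(stats::runif(n) < p, "positive", "negative")
  data.frame(er = draw(marginals$er_positive),
             pr = draw(marginals$pr_positive),
             ecad = draw(marginals$ecad_positive),
             her2 = draw(marginals$her2_positive),
             arid1a = draw(marginals$arid1a_positive),
             pten = draw(marginals$pten_positive),
             l1cam = draw(marginals$l1cam_positive),
             stringsAsFactors = FALSE)
}

sim_marginal_features <- function(n, marginals) {
  subtype <- sample(scheme_levels("promise"), n, replace = TRUE,
                    prob = sim_group_tables()$promise$proportions)
  # histology and grade are tilted towards NEEC / high grade for p53abn so
  # the printed marginals are matched in expectation
  p_neec <- ifelse(subtype == "p53abn", 0.70,
                   (1 - marginals$histology_eec - 0.70 * 34 / 293) /
                     (1 - 34 / 293))
  histology <- ifelse(stats::runif(n) < p_neec, "NEEC", "EEC")
  p_g3 <- ifelse(subtype == "p53abn", 0.75,
                 (marginals$grade[["G3"]] - 0.75 * 34 / 293) / (1 - 34 / 293))
  u <- stats::runif(n)
  g12 <- marginals$grade[["G1"]] /
    (marginals$grade[["G1"]] + marginals$grade[["G2"]])
  grade <- ifelse(u < p_g3, "G3",
                  ifelse(stats::runif(n) < g12, "G1", "G2"))
  si <- sample(names(marginals$stage_invasion), n, replace = TRUE,
               prob = marginals$stage_invasion)
  lvsi <- ifelse(stats::runif(n) < marginals$lvsi_positive,
                 "positive", "negative")
  wl <- pole_whitelist()
  pole_variant <- rep("", n)
  is_pole <- subtype == "POLE"
  pole_variant[is_pole] <- sample(wl, sum(is_pole), replace = TRUE)
  nonpath <- !is_pole &
    stats::runif(n) < marginals$pole_nonpathogenic_edm /
      max(1 - marginals$pole_pathogenic, 1e-12)
  pole_variant[nonpath] <- sample(c("T278M", "N363K", "A465V"),
                                  sum(nonpath), replace = TRUE)
  mmr <- ifelse(subtype == "MMRd", "deficient",
                ifelse(is_pole & stats::runif(n) < 0.2, "deficient",
                       "proficient"))
  p53 <- ifelse(subtype == "p53abn", "abnormal",
                ifelse(is_pole & stats::runif(n) < 0.1, "abnormal",
                       "wildtype"))
  ctnnb1 <- ifelse(stats::runif(n) < marginals$ctnnb1_mutated,
                   "mutated", "wildtype")
  data.frame(histology = histology, grade = grade,
             myometrial_invasion = sub("^.*\\.", "", si),
             figo_stage = sub("\\..*$", "", si),
             lvsi = lvsi, pole_variant = pole_variant,
             mmr_status = mmr, p53_ihc = p53, ctnnb1_exon3 = ctnnb1,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under the configured conditions (see [sim_config()]).
#' The cohort passes [validate_cohort()] before missingness masking; masking
#' only introduces NE states. In group_anchored mode the anchored labels are
#' attached as the `anchor` attribute (a data.frame of `patient_id`,
#' `group`) and agree with [classify_cohort()] on the unmasked records by
#' construction.
#'
#' @param config A [sim_config()].
#' @return Cohort data.frame with attributes `sim_config` and (in anchored
#'   mode) `anchor`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  lev <- scheme_levels(config$group_scheme)

  if (config$mode == "group_anchored") {
    group <- sample(lev, n, replace = TRUE, prob = config$group_proportions)
    features <- vector("list", length(lev))
    idx <- vector("list", length(lev))
    for (g in seq_along(lev)) {
      which_g <- which(group == lev[g])
      idx[[g]] <- which_g
      if (length(which_g) > 0) {
        features[[g]] <- feature_bundle_for_group(
          lev[g], config$group_scheme, length(which_g),
          config$feature_marginals)
      }
    }
    feat <- do.call(rbind, features)[order(unlist(idx)), , drop = FALSE]
  } else {
    feat <- sim_marginal_features(n, config$feature_marginals)
    labelled <- classify_cohort(
      cbind(patient_id = as.character(seq_len(n)), feat,
            stringsAsFactors = FALSE),
      config$group_scheme)
    group <- labelled$label
    if (anyNA(group)) {
      stop("marginal-mode features produced unclassifiable records before masking; check the marginals")
    }
  }

  t_event <- numeric(n)
  for (g in lev) {
    sel <- group == g
    t_event[sel] <- sim_event_times(sum(sel), config$five_year_rfs[[g]],
                                    config$weibull_shape)
  }
  cens <- censoring_times(n, config)
  rfs_event <- as.integer(t_event <= cens)
  rfs_time <- pmin(t_event, cens)

  lambda_post <- log(2) / config$post_relapse_median_months
  death <- t_event + stats::rexp(n, lambda_post)
  os_event <- as.integer(rfs_event == 1L & death <= cens)
  os_time <- ifelse(rfs_event == 1L, pmin(death, cens), cens)

  age <- pmin(pmax(round(stats::rnorm(n, 65, 10)), 30), 95)
  cohort <- cbind(
    data.frame(patient_id = sprintf("SYN-%05d", seq_len(n)),
               age_years = age, stringsAsFactors = FALSE),
    feat[, c("histology", "grade", "myometrial_invasion", "figo_stage",
             "lvsi", "pole_variant", "mmr_status", "p53_ihc",
             "ctnnb1_exon3")],
    sim_biomarkers(n, config$feature_marginals),
    data.frame(rfs_time_months = round(rfs_time, 2), rfs_event = rfs_event,
               os_time_months = round(os_time, 2), os_event = os_event)
  )
  rownames(cohort) <- NULL

  bad <- validate_cohort(cohort)
  if (nrow(bad) > 0) {
    stop("internal error: generated cohort fails validation: ",
         paste(unique(bad$rule), collapse = ", "))
  }

  if (length(config$missingness) > 0) {
    for (col in names(config$missingness)) {
      mask <- stats::runif(n) < config$missingness[[col]]
      cohort[[col]][mask] <- "NE"
    }
  }

  attr(cohort, "sim_config") <- config
  if (config$mode == "group_anchored") {
    attr(cohort, "anchor") <- data.frame(patient_id = cohort$patient_id,
                                         group = group,
                                         stringsAsFactors = FALSE)
  }
  cohort
}
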