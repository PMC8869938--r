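---
title: "Methods: risk classifiers, survival evaluation and the calibrated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk classifiers, survival evaluation and the calibrated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endorisk)
```

This vignette is the package's own account of its methods: the rule engines
and their edge-case semantics, the survival statistics and their numerical
conventions, the imputation procedure, what the synthetic-cohort generator
does and does not emulate, and the design choices made where the design was
genuinely open.

## The cohort schema

A cohort is a plain data.frame, one row per patient, with 22 fixed columns
(`cohort_columns()`): clinicopathological fields (age in years, histology
EEC/NEEC, grade G1–G3, myometrial invasion none / <50% / ≥50%, FIGO stage
IA/IB/II, binary LVSI), molecular calls (a free-text POLE amino-acid token,
MMR status, p53 IHC, CTNNB1 exon-3 status, and seven binary IHC biomarkers),
and two censored endpoints in months: relapse-free survival (surgery to
first recurrence or disease death) and disease-specific overall survival
(surgery to disease death; other deaths are censorings upstream of this
schema). Two conventions matter:

- **NE is a value, not an absence.** Markers that were assessed but could
  not be called carry the explicit token `"NE"`. Imputation is therefore an
  explicit, logged transformation, never a side effect of NA handling. An
  empty `pole_variant` means wild type, not missing.
- **Stage and depth must cohere.** FIGO IA requires invasion none or <50%,
  IB requires ≥50%; `validate_cohort()` reports every violation (plus
  RFS > OS, duplicate ids, negative times) with the patient id and rule
  name, and is order-independent.

Tumour size is deliberately absent from the schema: no classifier rule or
reported statistic consumes it, and no cut-off is established for it in this
setting.

## The four rule engines

All four engines are pure, deterministic and total over the vocabulary:
every input combination yields exactly one group label or one explicit
`"unclassifiable: <reason>"` token. There is no silent default — when a
rule needs an LVSI call and finds NE, the caller decides whether to impute.

**2016 classifier** (clinicopathological, stage I–II domain): low = stage
IA endometrioid G1–G2 LVSI−; intermediate = stage IB endometrioid G1–G2
LVSI−; high-intermediate = stage IA endometrioid G3 (any LVSI) or stage I
endometrioid G1–G2 LVSI+; high = stage IB endometrioid G3, stage II, or any
non-endometrioid histology.

**ProMisE**: POLE if the POLE token is on the pathogenic
exonuclease-domain whitelist; else MMRd if MMR-deficient; else p53abn if
p53-aberrant; else NSMP. The precedence POLE → MMRd → p53abn → NSMP is the
convention of the modified ProMisE cascade (sequencing first, IHC second);
the result is invariant to the values of dominated markers. The 11-variant
whitelist ships as a JSON config file (`pole_whitelist()`), not code,
because it belongs to an external consensus that may be revised;
exonuclease-domain alterations outside it are not used for classification.
Outside the POLE branch, an NE marker that could change the call (NE MMR
anywhere; NE p53 in an MMR-proficient tumour) is unclassifiable rather than
guessed.

**2020 classifier**: POLE → low; p53abn (or NEEC) with myometrial invasion
→ high, without invasion → intermediate; MMRd/NSMP endometrioid tumours
follow stage, binary grade and LVSI (IA low-grade LVSI− → low; IB low-grade
LVSI− or IA high-grade LVSI− → intermediate; LVSI+ stage I, IB high-grade,
or stage II → high-intermediate). Two collapses were forced by the data
model and are fixed package policy: the guideline's focal/substantial LVSI
distinction is unavailable when LVSI is recorded as binary, so "positive"
maps to the substantial-LVSI branch; and all NEEC histologies are treated
uniformly (the serous / clear-cell / undifferentiated subdivisions are not
recorded).

**Three-tier proposal**: low and high pass through from the 2020
classifier; the two intermediate groups merge, CTNNB1-mutated cases moving
to high and wild-type cases forming the redefined intermediate group.
Changing CTNNB1 from wild type to mutated can never lower the label
(monotone severity), the proposal's low group always equals the 2020 low
group, and its high group is a superset of the 2020 high group. A CTNNB1
call still NE after imputation is treated as wild type — with mutation
prevalence around 8.5% of evaluable cases this is the conservative default,
and it is applied visibly at the proposal stage only.

## Survival statistics

**Kaplan–Meier** estimation delegates to `survival::survfit`; the
`km_curve` object keeps the event-time steps, at-risk counts, Greenwood
variance $\widehat{\mathrm{Var}}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
d_i / (n_i(n_i - d_i))$, and pointwise CIs on the log–log scale (stable
near 0 and 1; α = 0.05 throughout). Censorings tied with an event time are
processed after the events. `survival_at(curve, 60)` is the five-year rate;
lookups beyond the last observed time return the last step with an explicit
extrapolation warning rather than NA.

**Cox fits** use `survival::coxph` with Efron tie handling by default
(Breslow selectable; the choice is recorded on every fit). A constant
covariate is an error; monotone-likelihood non-convergence (perfect
separation) sets `converged = FALSE` on the result instead of returning
silent numbers. Per-classifier hazard ratios use the ordinal coding low =
1, …, high = k (`cox_ordinal_by_group`), so a single HR is the per-one-step
increase in risk group; the integer map is stored in `covariate_coding`,
and empty levels are skipped with the remaining ranks kept consecutive.
For ProMisE the "severity order" is the classifier's conventional listing
POLE, MMRd, NSMP, p53abn — the package does not re-sort molecular subtypes
by observed outcome, which would leak the endpoint into the coding.

**Concordance** is implemented in the package (not delegated) because its
pair-level definition is part of the contract: a pair is permissible iff
the smaller time belongs to an event (tied times: iff exactly one member is
an event, the event member counting as shorter-lived); a permissible pair
is concordant when the shorter-lived patient has the higher risk score;
score ties contribute ½. Then
$c = (C + \tfrac{1}{2}T)/(C + D + T)$. The counts $C, D, T$ are exposed, so
the strict Goodman–Kruskal gamma variant — $(C-D)/(C+D)$, rescaled to
[0, 1] — is available from the same enumeration (`gamma_rescaled`); the two
coincide when there are no score ties. The test suite checks the
implementation pair-for-pair against an independent brute-force enumerator
on a thousand random small instances and against `survival::concordance` on
censored data. Classifier c-indexes are computed on the ordinal group score
— the classifier's only output; any strictly monotone transform (including
the Cox linear predictor under ordinal coding) gives the identical value.

**Univariate screens** use the standard codings (age >60 vs ≤60, EEC vs
NEEC, high vs low grade, invasion yes/no, LVSI +/−, ordinal FIGO stage,
marker positive vs negative, CTNNB1 mutated vs wild type), complete-case
per covariate; a covariate left degenerate after NE exclusion yields a
no-fit entry, not numbers. `merged_intermediate_screen` restricts to the
2020 intermediate ∪ high-intermediate stratum — the stratum whose survival
curves overlap — and screens the add-on biomarkers there.

## Predictive-mean-matching imputation

NE molecular cells are completed by predictive mean matching aggregated
over repeated runs: each run regresses the target on the
clinicopathological predictors over complete cases, draws coefficients from
their sampling distribution (residual variance from a scaled inverse
chi-square draw, coefficients from the corresponding normal), predicts for
the missing rows, and donates the observed category of one of the
`k_donors = 5` nearest complete-case predictions. Because only observed
values are donated, imputations are always members of the observed category
set. The final completion takes, per cell, the **modal** value across
`n_runs = 1000` independently seeded runs (run seeds drawn reproducibly
from the master seed), with ties broken by the fixed schema category order
— ties are rare at 1000 runs, and the break is logged per cell along with
the full vote counts.

Open internals decided here: a categorical target with $L$ observed levels
is handled as $L$ indicator regressions with squared distance summed over
the $L$ prediction dimensions (for the mostly binary targets this reduces
to matching on a single predicted probability); the default predictor set
is the clinicopathological block (age, histology, grade, invasion, stage,
LVSI), configurable; rows with an NE predictor cannot serve as donors and
fall back, like degenerate designs, to an empirical-distribution donor draw
that is flagged in the run output. No multiple-imputation inference is
attempted — the procedure collapses to a single modal completion by design.

## The synthetic-cohort generator

The generator exists so that every stage of the pipeline is testable
without patient data. Its defaults are the study conditions: n = 293;
group proportions per classifier (e.g. 145/60/50/38 for the 2020 groups,
145/100/48 for the three tiers); per-group five-year RFS rates (93.9 /
79.5 / 72.2 / 41.5% for 2020; 93.9 / 79.1 / 42.7% for the three tiers);
marginal frequencies (88.4% endometrioid, 80.2% low grade, 18% LVSI+,
CTNNB1 mutated 23/272 of evaluable, biomarker positivities from the
published distribution); per-column NE rates; and censoring with a
75-month median follow-up.

- **Event model.** Group-conditional exponential RFS with
  $\lambda_g = -\ln S_g(60)/60$ (`calibrate_hazard`), the minimal
  one-parameter model that reproduces the published five-year rates
  exactly in expectation. A Weibull shape is exposed for sensitivity
  checks; the scale is re-solved so $S(60)$ is preserved.
- **Censoring.** Uniform accrual over 144 months (a 12-year accrual
  window) with an administrative horizon of 147 months gives censoring
  times uniform on [3, 147] — median 75 months, matching the published
  median follow-up. The true censoring process is not described beyond
  that median, so this is a declared approximation, independent of event
  times.
- **Disease-specific OS.** Only relapsing patients can die of disease:
  OS = RFS event time + an exponential post-relapse survival, censored at
  the same administrative time. The post-relapse median is 24 months, a
  figure chosen once as clinically realistic for relapsed early-stage
  disease and consistent with roughly 26 disease deaths per 43 relapses;
  it is a config parameter, not a calibrated quantity.
- **group_anchored mode** draws the group label first, then a feature
  bundle the corresponding engine maps back to exactly that label. Bundles
  come from an exhaustive enumeration of the classifier-relevant
  cross-product (1152 schema-consistent combinations), labelled once by
  the engines themselves and sampled with weights equal to the product of
  marginal frequencies — so round-tripping (`classify_cohort` equals the
  anchor) holds by construction and is still tested, and cohort-level
  marginals stay close to the published ones without being forced.
- **marginal mode** draws features first and derives labels with the
  engines. The joint distribution is under-determined by printed
  marginals; the dependency structure is deliberately minimal: molecular
  subtype is linked to histology and grade (p53abn tumours are 70%
  non-endometrioid and 75% high grade, with the complementary rates solved
  so the overall marginals still hold), stage is linked to invasion depth
  by the schema constraint, and everything else is conditionally
  independent. The G1:G2 split within low grade (50:30.2) and the small NE
  rates for MMR and p53 (2% each; the published table reports those
  columns post-imputation) are fixed package choices.
- **Masking last.** Cohorts are schema-valid before missingness masking;
  masking only introduces NE states.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: patient-level covariate correlations beyond the
stated links (e.g. age is prognostically inert in the simulator),
non-proportional or non-exponential hazards within groups, competing risks,
treatment effects, informative censoring, and inter-observer variability in
the underlying pathology calls. Parameter-recovery results on this
generator validate the estimation machinery, not the clinical claims.

## Reporting surface

`build_classifier_report` assembles, for one scheme and endpoint, the group
distribution, per-group 60-month KM rates with CIs, the ordinal Cox fit,
the ordinal-score c-index and the log-rank test, all on the same classified
records; unclassifiable records are counted, never silently dropped, and
group sizes, event counts and pair counts reconcile across the
sub-statistics. `sankey_matrix` gives the reclassification contingency
table between two schemes (patients conserved; diagonal iff the labellings
agree), with a `{nodes, links}` payload for standard Sankey renderers.
`evaluate_proposal` builds the 2020 and three-tier reports on exactly the
same patients and returns the c-index delta; with zero CTNNB1 mutations the
proposal report reduces to the 2020 report with merged intermediates.
Display rounding follows the reporting convention (one decimal for
percentages, two for HRs and c-indexes); the stored objects keep full
precision.

## Problem sizes and numerical conventions in the checks

The test suite sizes its simulations so the whole run completes in well
under a minute while keeping Monte-Carlo error far inside the asserted
tolerances: engine totality over the 13k-combination cross-product; exact
concordance agreement on 1000 instances of n ≤ 30; KM CI coverage over 500
replicates of n = 200; Cox recovery at n = 5000 (within 3 standard
errors); pooled five-year-rate recovery over 200 replicates of the
published group sizes (±1.5–2 percentage points); CTNNB1 hazard-ratio
recovery as exp(mean log HR) over 500 replicates of n = 110 (±15%
relative); generator calibration at 50,000 patients per group (±1
percentage point); imputation determinism at 100 runs.

## Known limitations

- The rule engines cover the stage I–II domain only; stage III–IV branches
  of the 2020 guideline are out of scope, as are wet-lab protocols and
  variant-effect prediction (POLE and CTNNB1 status enter as pre-called
  tokens).
- The c-index advantage of the three-tier proposal over the 2020
  classifier under the proposal's own generating model is systematic but
  small (about +0.013 at very large n), comparable to its
  replicate-to-replicate variability at a single-study cohort size of
  ~300; single-cohort comparisons of two c-indexes at this scale are
  therefore noisy, and the seeded-superiority check in the test suite
  quantifies exactly this.
- No multivariable-adjusted Cox models, time-varying covariates or
  competing-risks machinery: the evaluation mirrors the univariate and
  ordinal-group analyses it was built for.
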