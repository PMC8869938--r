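# endorisk

Risk stratification and survival evaluation for early-stage (FIGO I–II)
endometrial cancer.

About 15% of early-stage endometrial carcinomas recur, and three
stratification tools are in clinical use to find those patients: the
**ESMO-ESGO-ESTRO 2016** classifier (clinicopathological: histology, grade,
stage, LVSI), the **ProMisE** molecular classifier (POLE / MMRd / NSMP /
p53abn, from POLE exonuclease-domain sequencing and MMR/p53
immunohistochemistry), and the **ESGO-ESTRO-ESP 2020** classifier, which
integrates both. None of them separates the two intermediate prognostic
groups well. `endorisk` implements all three as pure, total rule engines,
plus a **three-tier stratification** that augments the 2020 classifier with
*CTNNB1* exon-3 mutation status:

- low → low, high → high (unchanged);
- intermediate ∪ high-intermediate → **high** if *CTNNB1*-mutated,
  otherwise the redefined **intermediate** group.

Around the engines the package ships the full evaluation machinery for
censored follow-up data:

- Kaplan–Meier product-limit curves with Greenwood variance and log–log
  pointwise CIs (`km_estimate`, `survival_at`), via the `survival` package;
- Cox proportional-hazards fits with Efron/Breslow ties (`cox_fit`) and the
  ordinal-group coding low = 1, …, high = k that yields the per-step hazard
  ratio HR = exp(β) reported per classifier (`cox_ordinal_by_group`);
- a censoring-aware concordance index with Harrell permissible-pair rules
  and exposed pair counts, c = (C + ½T) / (C + D + T)
  (`concordance_index`), 0.5 = random, 1 = perfect;
- k-group log-rank tests and univariate Cox screens with the standard
  covariate codings (`logrank_test`, `univariate_screen`,
  `merged_intermediate_screen`);
- predictive-mean-matching imputation for NE ("not evaluable") molecular
  calls, aggregated as the modal value over many independently seeded runs
  (`pmm_mode_impute`);
- a synthetic-cohort generator calibrated to published group proportions,
  per-group five-year relapse-free survival rates (via the closed form
  λ = −ln S(60) / 60), marginal feature frequencies and a censoring model
  with 75-month median follow-up (`sim_config`, `generate_cohort`), so the
  whole pipeline is testable without patient data;
- report builders: per-classifier comparison tables, reclassification
  (Sankey) transition matrices, and the side-by-side evaluation of the
  three-tier proposal (`build_classifier_report`, `sankey_matrix`,
  `evaluate_proposal`).

## Worked example

Simulate a cohort of 293 patients anchored on the three-tier groups (the
generator defaults encode the published group sizes, five-year rates and
marginal frequencies), impute the NE molecular cells, screen the merged
intermediate groups, and compare the classifiers:

```r
library(endorisk)

cohort    <- generate_cohort(sim_config(group_scheme = "proposal", seed = 2024))
completed <- pmm_mode_impute(cohort, imputation_config(n_runs = 200, seed = 2024))
nrow(completed$log)   # 42 cells imputed

scr <- merged_intermediate_screen(completed$cohort)
scr$rfs[scr$rfs$covariate == "ctnnb1", ]
#>   covariate  n n_events   hr ci_low ci_high p_value
#>      ctnnb1 99       25 3.76   1.56    9.03  0.0031

evaluate_proposal(completed$cohort, endpoint = "rfs")
```

```
Proposal evaluation on 289 patients: c-index 0.78 (proposal) vs 0.77 (2020), delta +0.010

Classifier report: c2020, endpoint RFS, n = 289 classified (0 unclassifiable)
  low                n = 152 ( 52.6%), events =   8, 60-month rate = 95.4%
  intermediate       n =  63 ( 21.8%), events =  16, 60-month rate = 79.9%
  high_intermediate  n =  36 ( 12.5%), events =   9, 60-month rate = 74.2%
  high               n =  38 ( 13.1%), events =  23, 60-month rate = 48.1%
  ordinal Cox: HR 2.32 (95% CI 1.85-2.90), p = 1.89e-13
  c-index: 0.77
  log-rank: chi-square 78.54 on 3 df, p = 6.32e-17

Classifier report: proposal, endpoint RFS, n = 289 classified (0 unclassifiable)
  low                n = 152 ( 52.6%), events =   8, 60-month rate = 95.4%
  intermediate       n =  87 ( 30.1%), events =  18, 60-month rate = 82.6%
  high               n =  50 ( 17.3%), events =  30, 60-month rate = 47.1%
  ordinal Cox: HR 4.13 (95% CI 2.89-5.91), p = 6.1e-15
  c-index: 0.78
  log-rank: chi-square 92.64 on 2 df, p = 7.64e-21
```

Within the merged intermediate stratum, *CTNNB1* mutation carries a hazard
ratio of 3.76 for relapse (the generating model put it there), and folding
that marker into the classifier sharpens the separation: the ordinal
per-step HR rises from 2.32 to 4.13 and the worst tier's 60-month
relapse-free rate drops from 74.2% (high-intermediate) to 47.1% while the
intermediate tier's rises to 82.6%.

Cohorts round-trip through a plain CSV schema (`read_cohort`,
`write_cohort`, `validate_cohort`), with "NE" as the explicit
not-evaluable state, so real patient tables can be substituted for the
simulator anywhere.

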