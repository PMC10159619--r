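# PRSeval

Evaluation of polygenic risk scores (PRSs) in prospective cohorts, under
competing mortality.

Published PRSs — weighted sums of risk-allele dosages,
`PRS = Σ_k β_k x_k` with `β_k` a log odds ratio and `x_k ∈ [0, 2]` the
effect-allele dosage — are typically trained in European-ancestry GWAS, and
their transferability to other populations has to be demonstrated, not
assumed. PRSeval implements the full evaluation a cancer-epidemiology
group would run on a genotyped prospective cohort with registry follow-up:

- **Scoring** — parse PGS-Catalog-format weight files, apply variant QC
  (imputation INFO ≥ 0.8, MAF ≥ 0.01, HWE exact p ≥ 1e-6, call rate
  ≥ 0.95, biallelic), harmonize alleles against the genotype panel
  (direct / effect-other swapped / strand complement; strand-ambiguous
  palindromic variants dropped), and compute raw and z-standardized
  scores, with mean imputation of missing dosages.
- **Distribution** — Welch two-sample t-test of standardized PRS in
  incident cases versus non-cases.
- **Discrimination** — AUC as the Mann–Whitney concordance probability
  (ties ½) with DeLong 95% CI, an age-adjusted logistic variant, and a
  cumulative/dynamic time-dependent AUC at 5 years with Kaplan–Meier
  censoring weights; best score selected by unadjusted AUC.
- **Hazard-ratio stratification** — Cox proportional-hazards models on
  time since recruitment (Efron ties, age-adjusted), with PRS quintiles
  against the middle quintile as reference, a per-SD model with a fully
  adjusted covariate set, an ordinal Wald trend test, and the
  Grambsch–Therneau score test on scaled Schoenfeld residuals for the
  proportional-hazards assumption.
- **Absolute risk** — solves the constrained baseline hazard
  `λ_m(a) = Σ_g π_g(a) λ0(a) RR_g` iteratively from age-band population
  incidence and all-cause mortality, where the 20 five-percentile PRS
  bands carry `RR_g = exp(β·E[Z | band])` and the at-risk weights
  `π_g(a)` deplete under group-specific cancer hazard plus shared
  mortality; 5-year absolute risks per age and band treat death as a
  competing event.
- **Calibration** — expected versus observed 5-year risk by PRS decile,
  an OLS calibration slope with 95% CI (slope > 1: underestimation;
  < 1: overestimation), and a Hosmer–Lemeshow chi-square with df = 8.
- **Synthetic cohort generator** — Hardy–Weinberg genotypes, scoring
  files, proportional-hazards cancer outcomes with competing death and
  20-year administrative censoring, and the analytic rate table implied
  by the generator, so the full pipeline is testable without access to
  restricted cohort data.

## Worked example

```r
library(PRSeval)

cfg    <- simConfig(nSamples = 20000L, nVariants = 100L, seed = 1L)
config <- simulateDemo(cfg, "demo")     # writes scorefiles, genotypes,
                                        # cohort CSV, rate CSVs
report <- runPipeline(config)
st <- report$strata$female
st$bestPrs
#> [1] "PGSSIM001"
st$scores[[st$bestPrs]]$discrimination[c("auc", "ciLow", "ciHigh")]
#> AUC 0.618 (95% CI 0.592-0.644)
st$hr$table
#>   group    n n_cases    hr ci_low ci_high divergent
#> 1     1 2246      39 0.453  0.310   0.662     FALSE
#> 2     2 2247      65 0.762  0.552   1.053     FALSE
#> 3     3 2247      85 1.000     NA      NA     FALSE
#> 4     4 2247     103 1.227  0.921   1.635     FALSE
#> 5     5 2247     133 1.581  1.204   2.075     FALSE
st$hr$perSD
#> HR 1.53 (1.39-1.68), p = 3.1e-18     (generating per-SD HR: 1.50)
st$calibration$slope
#> slope 0.98 (0.56-1.41)               (well-calibrated: 1)
```

The simulated cohort carries a true per-SD hazard ratio of 1.5 on the
first score; the evaluation recovers it (per-SD HR 1.53), ranks the
causal score above the half-overlapping second score, shows the expected
quintile gradient around the unit reference, and is calibrated (slope
0.98, Hosmer–Lemeshow p = 0.42). A thin command-line wrapper is
installed at `inst/scripts/prs-pipeline.R`
(`simulate` / `evaluate` subcommands).

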