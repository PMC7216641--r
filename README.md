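# lipofx

Bayesian treatment-effect models for NMR lipoprotein subclass panels.

`lipofx` is for statisticians and metabolomics researchers analysing
small two-arm lipid-lowering trials (the motivating setting is a
PCSK9-inhibitor trial with 16 treated and 14 placebo subjects profiled
on a Nightingale-style NMR panel at baseline and week 16). It provides
the two models such an analysis needs, with the missing-data handling
NMR panels require, plus a synthetic-cohort generator so the whole
pipeline can be validated without access to restricted patient data.

## The models

**Lognormal treatment-effect regression** (`fitTreatmentModel`). For a
metabolite with week-16 concentration *y*, treatment indicator *T* and
standardized log-baseline *x* (optionally statin *S* and ezetimibe *E*
indicators):

    log y ~ Normal(b0 + bT·T + bx·x [+ bS·S + bE·E], sigma)

The treatment effect is reported as a percent reduction
`100·(1 − exp(bT))` with its posterior mean and equal-tailed 95%
credible interval. Outcomes below the limit of detection are treated as
interval-censored parameters constrained to (0, minimal observed value);
QC-rejected outcomes are imputed from the model's predictive
distribution (missing at random). Priors are Normal(0, 2.5) /
half-Normal(0, 2.5); inflating them recovers least squares on log
outcomes, which the test suite uses as an oracle.

**Multilevel bivariate Lp(a)/subclass model** (`fitMultilevel`). For
treated subjects' paired log-Lp(a) and log-subclass concentrations
across the two visits, subject-specific intercepts and treatment
effects `[alpha_L, beta_L, alpha_y, beta_y]` are drawn from a 4-variate
normal with covariance `Sigma_subj`; the derived quantity is

    rho = Sigma_subj[1,4] / sqrt(Sigma_subj[1,1]·Sigma_subj[4,4])

the correlation between baseline Lp(a) and the subject-level subclass
treatment effect (negative rho = higher baseline Lp(a) goes with larger
reduction). The covariance prior uses the separation strategy (scaled
inverse-Wishart) so the correlation keeps a symmetric, weakly
informative prior whatever the data say about the variances; a fit whose
posterior rho interval stays ≥90% as wide as the prior interval is
flagged `uninformative`. Both models run on JAGS (Gibbs sampling) with
deterministic per-chain seeding.

Support machinery: validated cohort containers with exact-round-trip CSV
I/O (`readCohort`/`writeCohort`), the 14-subclass particle catalog with
diameters (`nightingaleCatalog`), unit conversions and Friedewald LDL-C,
baseline-characteristics tables with rank-sum and no-continuity
chi-square tests (`buildTable1`), posterior summaries with R-hat/ESS
(`summarizeDraws`), and forest plots (`forestPlot`).

## Worked example

Simulate the study conditions (16/14 subjects, published effect sizes,
detection limits, 3% QC rejection), then estimate the Lp(a) effect and
the Lp(a)/medium-VLDL coupling:

```r
library(lipofx)

cfg <- pcsk9TrialConfig(seed = 42)
cohort <- applyMissingness(generateCohort(cfg), cfg)
cohort
#> CohortDataset: 30 subjects (16 treated / 14 placebo), 1020 measurement records
#>   17 metabolites; status: observed 971, below_lod 27, qc_rejected 22
#>   (hidden truth channel present)

fit <- fitTreatmentModel(treatmentInputs(cohort, "Lp_a"),
                         sampler = samplerSettings(seed = 42))
percentChange(fit)
#> PosteriorSummary: 13.56 [6.796, 20.02]  (Rhat 1.002, ESS 1221)  [ok]
```

The generator's true Lp(a) reduction is 17%; this single 30-subject
replicate estimates 13.6% [6.8, 20.0] — the interval covers the truth,
and across replicates the coverage is the nominal 95% (the acceptance
suite measures it).

```r
treated <- subsetArm(cohort, 1)
ml <- fitMultilevel(treated, "M_VLDL_P",
                    sampler = samplerSettings(iterations = 10000,
                                              warmup = 2000, seed = 42))
baselineEffectCorrelation(ml)
#> PosteriorSummary: -0.3557 [-0.8122, 0.3501]  (Rhat 1.004, ESS 2767)  [warn_convergence]
```

The true correlation is −0.5; at 16 subjects the interval is wide, as it
must be. The `warn_convergence` flag here comes from the strict 1.01
R-hat threshold applied to the hyper-means, whose redundant
location/scale decomposition mixes slowly under Gibbs sampling — the
correlation itself has R-hat 1.004 (see the methods vignette,
`vignettes/lipoprotein-treatment-models.Rmd`).

```r
buildTable1(cohort, data.frame(variable = c("statin", "ezetimibe", "Lp_a"),
                               kind = c("count_pct", "count_pct", "median_iqr"),
                               digits = c(0, 0, 0)))
#>    variable       kind       treated       placebo   p_value       test
#> 1    statin  count_pct        6 (38)        8 (57) 0.2819793 chi_square
#> 2 ezetimibe  count_pct        6 (38)        2 (14) 0.1514456 chi_square
#> 3      Lp_a median_iqr 252 [206-313] 291 [138-338] 0.9502795   wilcoxon
```

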