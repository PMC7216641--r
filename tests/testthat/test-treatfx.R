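# Unit tests for the lognormal treatment-effect regression. Replicate
# studies at trial scale live in the acceptance suite; here single fits
# check recovery, the least-squares limit, censoring and invariances.

test_that("a null effect is recovered within Monte Carlo error", {
  cfg <- lpaOnlyConfig(seed = 41, effect = 0, n_treated = 100, n_placebo = 100)
  ds <- generateCohort(cfg)
  fit <- fitTreatmentModel(treatmentInputs(ds, "Lp_a"),
                           sampler = fastSampler(1))
  bT <- posteriorDraws(fit, "bT")[, 1]
  mcse <- sd(bT) / sqrt(fit@diagnostics$ess_min)
  # truth 0 lies within the posterior's own uncertainty
  expect_lt(abs(mean(bT)), sd(bT) + 2 * mcse)
})

test_that("a halving effect is recovered at n = 200 per arm", {
  cfg <- lpaOnlyConfig(seed = 42, effect = log(0.5), n_treated = 200,
                       n_placebo = 200)
  ds <- generateCohort(cfg)
  fit <- fitTreatmentModel(treatmentInputs(ds, "Lp_a"),
                           sampler = fastSampler(2))
  bT <- mean(posteriorDraws(fit, "bT")[, 1])
  expect_lt(abs(bT - log(0.5)), 0.05)
})

test_that("with inflated priors the posterior matches least squares on log y", {
  cfg <- lpaOnlyConfig(seed = 43, effect = log(0.83), n_treated = 100,
                       n_placebo = 100)
  ds <- generateCohort(cfg)
  inp <- treatmentInputs(ds, "Lp_a")
  fit <- fitTreatmentModel(inp, sampler = fastSampler(3, iterations = 2500,
                                                      warmup = 500),
                           priorScale = 1000)
  ols <- lm(log(inp@y) ~ inp@treatment + inp@x)
  draws <- posteriorDraws(fit, c("b0", "bT", "bx"))
  for (j in 1:3) {
    mcse <- sd(draws[, j]) / sqrt(coda::effectiveSize(draws[, j]))
    expect_lt(abs(mean(draws[, j]) - coef(ols)[j]), 2 * mcse + 1e-3)
  }
})

test_that("below-LOD imputations always respect the censoring interval", {
  cfg <- pcsk9TrialConfig(seed = 44)
  ds <- applyMissingness(generateCohort(cfg), cfg)
  fit <- fitTreatmentModel(treatmentInputs(ds, "XXL_VLDL_P"),
                           sampler = fastSampler(4))
  expect_gt(fit@n_below_lod, 0)
  imp <- imputationDraws(fit, censoredOnly = TRUE)
  expect_true(all(imp > 0))
  expect_true(all(imp < fit@lod_floor))
  # sigma draws are strictly positive
  expect_true(all(posteriorDraws(fit, "sigma") > 0))
})

test_that("shifting all log outcomes moves only the intercept", {
  cfg <- lpaOnlyConfig(seed = 45, n_treated = 60, n_placebo = 60)
  ds <- generateCohort(cfg)
  inp <- treatmentInputs(ds, "Lp_a")
  shift_const <- 2.5
  inp2 <- inp
  inp2@y <- inp@y * exp(shift_const)
  f1 <- fitTreatmentModel(inp, sampler = fastSampler(5))
  f2 <- fitTreatmentModel(inp2, sampler = fastSampler(5))
  b0_1 <- posteriorDraws(f1, "b0")[, 1]; b0_2 <- posteriorDraws(f2, "b0")[, 1]
  bT_1 <- posteriorDraws(f1, "bT")[, 1]; bT_2 <- posteriorDraws(f2, "bT")[, 1]
  mcse <- function(v, f) sd(v) / sqrt(f@diagnostics$ess_min)
  expect_lt(abs(mean(b0_2) - mean(b0_1) - shift_const),
            3 * (mcse(b0_1, f1) + mcse(b0_2, f2)))
  expect_lt(abs(mean(bT_2) - mean(bT_1)),
            3 * (mcse(bT_1, f1) + mcse(bT_2, f2)))
})

test_that("independent seeds agree within Monte Carlo error", {
  cfg <- lpaOnlyConfig(seed = 46, n_treated = 50, n_placebo = 50)
  ds <- generateCohort(cfg)
  inp <- treatmentInputs(ds, "Lp_a")
  f1 <- suppressWarnings(fitTreatmentModel(inp, sampler = fastSampler(100)))
  f2 <- suppressWarnings(fitTreatmentModel(inp, sampler = fastSampler(200)))
  b1 <- posteriorDraws(f1, "bT")[, 1]; b2 <- posteriorDraws(f2, "bT")[, 1]
  tol <- 3 * (sd(b1) / sqrt(f1@diagnostics$ess_min) +
              sd(b2) / sqrt(f2@diagnostics$ess_min))
  expect_lt(abs(mean(b1) - mean(b2)), tol)
})

test_that("constant adjustment indicators are dropped with a notice", {
  cfg <- lpaOnlyConfig(seed = 47, n_treated = 20, n_placebo = 20)
  ds <- generateCohort(cfg)
  s <- subjects(ds); s$ezetimibe <- 0L
  ds2 <- CohortDataset(s, measurements(ds))
  expect_message(
    fit <- fitTreatmentModel(treatmentInputs(ds2, "Lp_a"),
                             adjustLipidLowering = TRUE,
                             sampler = fastSampler(6)),
    "E constant")
  expect_equal(fit@dropped, "E")
  expect_true("bS" %in% fit@coef_names)
  expect_false("bE" %in% fit@coef_names)
})

test_that("an arm with too few observed outcomes is refused", {
  s <- tinySubjects(3, 3)
  m <- tinyMeasurements(s, "m1")
  wk_placebo <- m$visit == "week16" & m$subject_id %in% s$subject_id[s$arm == 0]
  m$status[wk_placebo] <- "qc_rejected"
  m$concentration[wk_placebo] <- NA
  ds <- CohortDataset(s, m)
  expect_error(fitTreatmentModel(treatmentInputs(ds, "m1")),
               "2 observed outcomes per arm")
})

test_that("percent change transforms log effects with its bounds", {
  expect_equal(percentChange(rep(0, 200))@mean, 0)
  s <- percentChange(rep(log(0.83), 200))
  expect_equal(s@mean, 17, tolerance = 1e-9)
  expect_equal(s@ci_low, 17, tolerance = 1e-9)
  # reductions never exceed 100%, increases are negative
  big <- percentChange(c(rep(-50, 150), rep(log(1.13), 150)))
  expect_lte(big@ci_high, 100)
  expect_equal(percentChange(rep(log(1.13), 200))@mean, -13, tolerance = 1e-9)
})

test_that("panel fits are catalog-ordered and isolate per-analyte failures", {
  cfg <- pcsk9TrialConfig(seed = 48)
  ds <- applyMissingness(generateCohort(cfg), cfg)
  # break one analyte: censor all treated week-16 values of S_HDL_P
  m <- measurements(ds)
  kill <- m$metabolite_id == "S_HDL_P" & m$visit == "week16"
  m$status[kill] <- "qc_rejected"; m$concentration[kill] <- NA
  ds2 <- CohortDataset(subjects(ds), m)
  analytes <- c("M_VLDL_P", "S_HDL_P", "L_LDL_P", "Lp_a")
  tab <- suppressMessages(suppressWarnings(
    fitPanel(ds2, analytes, sampler = fastSampler(7, iterations = 1000,
                                                  warmup = 400))))
  expect_equal(tab$analyte, c("M_VLDL_P", "L_LDL_P", "S_HDL_P", "Lp_a"))
  expect_true(is.na(tab$mean_reduction_pct[tab$analyte == "S_HDL_P"]))
  expect_match(tab$error[tab$analyte == "S_HDL_P"], "observed outcomes")
  expect_true(all(!is.na(tab$mean_reduction_pct[tab$analyte != "S_HDL_P"])))
  expect_equal(nrow(fitPanel(ds2, character())), 0)
})

test_that("panel ordering of effects follows the generator truth", {
  cfg <- pcsk9TrialConfig(seed = 49)
  ds <- applyMissingness(generateCohort(cfg), cfg)
  tab <- suppressMessages(suppressWarnings(
    fitPanel(ds, c("L_VLDL_P", "M_VLDL_P", "L_LDL_P", "M_HDL_P"),
             sampler = fastSampler(8, iterations = 1000, warmup = 400))))
  est <- setNames(tab$mean_reduction_pct, tab$analyte)
  # configured truths: 60%, 50%, 56%, -13%: VLDL reductions exceed the
  # medium-HDL increase, and the HDL effect keeps its sign
  expect_gt(est[["L_VLDL_P"]], est[["M_HDL_P"]])
  expect_gt(est[["M_VLDL_P"]], est[["M_HDL_P"]])
  expect_lt(est[["M_HDL_P"]], 0)
})
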