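test_that("generated cohorts have the configured dimensions and are reproducible", {
  cfg <- syntheticConfig(16, 14, rbind(
    metaboliteSpec("m1", 0, 0.3), metaboliteSpec("m2", 1, 0.3),
    metaboliteSpec("m3", 2, 0.3)), seed = 7)
  ds <- generateCohort(cfg)
  expect_equal(nrow(subjects(ds)), 30)
  expect_equal(nrow(measurements(ds)), 30 * 2 * 3)
  expect_true(all(measurements(ds)$status == "observed"))
  expect_true(all(measurements(ds)$concentration > 0))
  ds2 <- generateCohort(cfg)
  expect_identical(measurements(ds), measurements(ds2))
  expect_identical(subjects(ds), subjects(ds2))
})

test_that("null treatment effect gives arm-wise geometric-mean ratio near 1", {
  cfg <- lpaOnlyConfig(seed = 11, effect = 0, n_treated = 2000,
                       n_placebo = 2000)
  ds <- generateCohort(cfg)
  m <- measurements(ds); s <- subjects(ds)
  wk <- m[m$visit == "week16", ]
  arm <- s$arm[match(wk$subject_id, s$subject_id)]
  ratio <- exp(mean(log(wk$concentration[arm == 1])) -
               mean(log(wk$concentration[arm == 0])))
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("arm contrast of week-16 log means recovers the treatment effect", {
  cfg <- lpaOnlyConfig(seed = 6, effect = log(0.83), n_treated = 3000,
                       n_placebo = 3000)
  ds <- generateCohort(cfg)
  m <- measurements(ds); s <- subjects(ds)
  wk <- m[m$visit == "week16", ]
  arm <- s$arm[match(wk$subject_id, s$subject_id)]
  contrast <- mean(log(wk$concentration[arm == 1])) -
    mean(log(wk$concentration[arm == 0]))
  se <- sqrt(var(log(wk$concentration[arm == 1])) / sum(arm == 1) +
             var(log(wk$concentration[arm == 0])) / sum(arm == 0))
  expect_lt(abs(contrast - log(0.83)), 2 * se)
})

test_that("subject-effect quadruples converge to the configured covariance", {
  cfg <- pairOnlyConfig(seed = 3, n_treated = 5000)
  # near-zero residual noise so per-subject effects are read off the data
  cfg@pair$residual_sigma <- diag(2) * 1e-8
  target <- cfg@pair$sigma_subj
  ds <- generateCohort(cfg)
  m <- measurements(ds); s <- subjects(ds)
  treated <- s$subject_id[s$arm == 1]
  val <- function(metab, visit) {
    v <- m[m$metabolite_id == metab & m$visit == visit, ]
    log(v$concentration[match(treated, v$subject_id)])
  }
  aL <- val("Lp_a", "baseline"); bL <- val("Lp_a", "week16") - aL
  ay <- val("M_VLDL_P", "baseline"); by <- val("M_VLDL_P", "week16") - ay
  emp <- cov(cbind(aL, bL, ay, by))
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(emp - target) / frob(target), 0.05)
})

test_that("missingness mechanisms censor as specified and keep a truth channel", {
  cfg <- lpaOnlyConfig(seed = 9)
  ds <- generateCohort(cfg)
  # no LOD, no QC: unchanged
  same <- applyMissingness(ds, cfg)
  expect_identical(measurements(same)$concentration,
                   measurements(ds)$concentration)
  # infinite LOD: everything censored
  cfg_inf <- lpaOnlyConfig(seed = 9)
  cfg_inf@metabolites$lod <- Inf
  all_cens <- applyMissingness(ds, cfg_inf)
  expect_true(all(measurements(all_cens)$status == "below_lod"))
  expect_true(all(is.na(measurements(all_cens)$concentration)))
  # truth channel preserves the original values
  expect_identical(truthData(all_cens)$concentration,
                   measurements(ds)$concentration)
  expect_error(applyMissingness(all_cens, cfg), "fully observed")
})

test_that("QC rejection rate concentrates at its configured probability", {
  cfg <- lpaOnlyConfig(seed = 13, n_treated = 2500, n_placebo = 2500, qc = 0.1)
  ds <- applyMissingness(generateCohort(cfg), cfg)
  frac <- mean(measurements(ds)$status == "qc_rejected")
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
})

test_that("toggling missingness does not change the underlying values", {
  cfg <- lpaOnlyConfig(seed = 21, qc = 0.2)
  ds <- generateCohort(cfg)
  miss <- applyMissingness(ds, cfg)
  keep <- measurements(miss)$status == "observed"
  expect_identical(measurements(miss)$concentration[keep],
                   measurements(ds)$concentration[keep])
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(0, 14, metaboliteSpec("m1", 0, 1)), ">= 1")
  bad_pair <- list(lpa_id = "Lp_a", subclass_id = "M_VLDL_P",
                   means = rep(0, 4),
                   sigma_subj = diag(c(1, 1, 1, -1)),  # not positive definite
                   residual_sigma = diag(2))
  mets <- rbind(metaboliteSpec("Lp_a", 0, 1), metaboliteSpec("M_VLDL_P", 0, 1))
  expect_error(syntheticConfig(16, 14, mets, pair = bad_pair),
               "positive definite")
  expect_error(syntheticConfig(16, 14, metaboliteSpec("m1", 0, 1),
                               qc_missing_prob = 1.2), "\\[0,1\\]")
})

test_that("the trial-scale configuration encodes the published conditions", {
  cfg <- pcsk9TrialConfig(seed = 2)
  expect_equal(cfg@n_treated, 16L)
  expect_equal(cfg@n_placebo, 14L)
  mets <- cfg@metabolites
  expect_equal(mets$treatment_log_effect[mets$metabolite_id == "Lp_a"],
               log(0.83))
  expect_equal(mets$treatment_log_effect[mets$metabolite_id == "LDL_C"],
               log(0.33))
  S <- cfg@pair$sigma_subj
  expect_equal(S[1, 4] / sqrt(S[1, 1] * S[4, 4]), -0.5)
  # the two largest VLDL fractions carry detection limits
  expect_true(all(mets$lod[mets$metabolite_id %in%
                             c("XXL_VLDL_P", "XL_VLDL_P")] > 0))
  # and are frequently censored after treatment
  ds <- applyMissingness(generateCohort(cfg), cfg)
  m <- measurements(ds); s <- subjects(ds)
  wk_t <- m[m$visit == "week16" & m$metabolite_id == "XL_VLDL_P" &
              m$subject_id %in% s$subject_id[s$arm == 1], ]
  expect_gte(mean(wk_t$status == "below_lod"), 0.3)
})
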