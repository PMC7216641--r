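# Unit tests for the multilevel bivariate Lp(a)/subclass model.
# Replicate coverage studies live in the acceptance suite.

test_that("the generative correlation is recovered at 50 subjects", {
  # single-replicate posterior means scatter ~0.1 around truth at this n,
  # so recovery is asserted on the mean over a few replicate cohorts
  means <- numeric(4)
  for (r in seq_along(means)) {
    cfg <- pairOnlyConfig(seed = 50 + r, n_treated = 50)
    ds <- subsetArm(generateCohort(cfg), 1)
    fit <- suppressWarnings(
      fitMultilevel(ds, "M_VLDL_P", sampler = mlSampler(10 + r)))
    rho <- baselineEffectCorrelation(fit)
    means[r] <- rho@mean
    if (r == 1) {
      # a well-identified fit is never declared uninformative
      expect_false(rho@flag == "uninformative")
      draws <- posteriorDraws(fit, "rho")[, 1]
      expect_true(all(draws >= -1 & draws <= 1))
    }
  }
  expect_lt(abs(mean(means) - (-0.5)), 0.15)
})

test_that("an uncoupled generator centres the correlation at zero", {
  covers <- logical(6)
  for (r in seq_along(covers)) {
    cfg <- pairOnlyConfig(seed = 600 + r, n_treated = 30, rho = 0)
    ds <- subsetArm(generateCohort(cfg), 1)
    fit <- suppressWarnings(
      fitMultilevel(ds, "M_VLDL_P", sampler = mlSampler(r, iterations = 2500)))
    s <- baselineEffectCorrelation(fit)
    covers[r] <- s@ci_low <= 0 && s@ci_high >= 0
  }
  expect_gte(sum(covers), 5)
})

test_that("correlation summaries follow the closed form on covariance draws", {
  # identity covariance on all draws: rho identically zero
  id <- array(diag(4), dim = c(4, 4, 200))
  s0 <- baselineEffectCorrelation(id)
  expect_equal(c(s0@mean, s0@ci_low, s0@ci_high), c(0, 0, 0))
  # off-diagonal 0.5 * sd1 * sd4 gives rho 0.5 exactly
  S <- diag(c(4, 1, 1, 9)); S[1, 4] <- S[4, 1] <- 0.5 * 2 * 3
  s5 <- baselineEffectCorrelation(array(S, dim = c(4, 4, 200)))
  expect_equal(c(s5@mean, s5@ci_low, s5@ci_high), c(0.5, 0.5, 0.5))
})

test_that("the prior on the subject-level correlation is centred and wide", {
  pr <- priorCorrelationDraws(n = 4000, seed = 1)
  expect_true(all(pr >= -1 & pr <= 1))
  expect_lt(abs(mean(pr)), 0.05)
  # weakly informative and symmetric: most of (-1, 1) retains prior mass
  ci <- quantile(pr, c(0.025, 0.975))
  expect_lt(ci[[1]], -0.8)
  expect_gt(ci[[2]], 0.8)
  expect_lt(abs(ci[[1]] + ci[[2]]), 0.05)
  expect_identical(priorCorrelationDraws(n = 100, seed = 3),
                   priorCorrelationDraws(n = 100, seed = 3))
})

test_that("placebo subjects and absent analytes are refused", {
  cfg <- pairOnlyConfig(seed = 53, n_treated = 10)
  ds <- generateCohort(cfg)  # still contains the placebo subject
  expect_error(fitMultilevel(ds, "M_VLDL_P"), "treated arm")
  tr <- subsetArm(ds, 1)
  expect_error(fitMultilevel(tr, "IDL_P"), "not present")
})

test_that("a subject with one sample is kept latent with a notice", {
  cfg <- pairOnlyConfig(seed = 54, n_treated = 12)
  ds <- subsetArm(generateCohort(cfg), 1)
  m <- measurements(ds)
  # first subject's week-16 pair sample was never assayed; a filler
  # metabolite keeps the visit represented in the container
  drop <- m$subject_id == subjects(ds)$subject_id[1] & m$visit == "week16"
  filler <- data.frame(subject_id = subjects(ds)$subject_id,
                       visit = rep(c("baseline", "week16"),
                                   each = nrow(subjects(ds))),
                       metabolite_id = "Albumin", concentration = 45,
                       status = "observed", stringsAsFactors = FALSE)
  ds2 <- CohortDataset(subjects(ds), rbind(m[!drop, ], filler),
                       truth = data.frame())
  fit <- suppressWarnings(
    fitMultilevel(ds2, "M_VLDL_P", sampler = fastSampler(12)))
  expect_match(paste(fit@notes, collapse = " "), "latent")
  expect_equal(length(fit@subject_ids), 12)
})

test_that("subclass tables are catalog-ordered, isolated and repeatable", {
  entries <- catalogEntries(nightingaleCatalog())
  small_cat <- SubclassCatalog(entries[entries$subclass_id %in%
                                         c("M_VLDL_P", "IDL_P"), ])
  cfg <- pairOnlyConfig(seed = 55, n_treated = 12)
  ds <- subsetArm(generateCohort(cfg), 1)
  ds <- CohortDataset(subjects(ds), measurements(ds), catalog = small_cat)
  st <- fastSampler(13, iterations = 1000, warmup = 400)
  tab <- runAllSubclasses(ds, sampler = st)
  expect_equal(tab$subclass, c("M_VLDL_P", "IDL_P"))
  expect_false(is.na(tab$rho_mean[1]))
  expect_match(tab$error[2], "not present")  # IDL absent from this cohort
  tab2 <- runAllSubclasses(ds, sampler = st)
  expect_identical(tab, tab2)
  empty <- CohortDataset(subjects(ds), measurements(ds),
                         catalog = SubclassCatalog())
  expect_equal(nrow(runAllSubclasses(empty, sampler = st)), 0)
})

test_that("only the coupled subclass shows a material correlation", {
  # cohort with the Lp(a)/medium-VLDL pair coupled at -0.5 and two
  # independent subclasses
  sds <- c(0.40, 0.10, 0.40, 0.35)
  R <- diag(4); R[1, 4] <- R[4, 1] <- -0.5
  mets <- rbind(
    metaboliteSpec("Lp_a", log(230), 0.4),
    metaboliteSpec("M_VLDL_P", log(5.2), 0.4),
    metaboliteSpec("S_VLDL_P", log(17), 0.35, treatment_log_effect = log(0.61),
                   residual_log_sd = 0.16),
    metaboliteSpec("IDL_P", log(120), 0.25, treatment_log_effect = log(0.47),
                   residual_log_sd = 0.22))
  cfg <- syntheticConfig(60, 1, mets,
                         pair = list(lpa_id = "Lp_a", subclass_id = "M_VLDL_P",
                                     means = c(log(230), log(0.83), log(5.2), log(0.5)),
                                     sigma_subj = diag(sds) %*% R %*% diag(sds),
                                     residual_sigma = diag(c(0.08, 0.12))^2),
                         seed = 56)
  ds <- subsetArm(generateCohort(cfg), 1)
  entries <- catalogEntries(nightingaleCatalog())
  ds <- CohortDataset(subjects(ds), measurements(ds),
                      catalog = SubclassCatalog(
                        entries[entries$subclass_id %in%
                                  c("M_VLDL_P", "S_VLDL_P", "IDL_P"), ]))
  tab <- suppressWarnings(runAllSubclasses(ds, sampler = mlSampler(14)))
  coupled <- tab[tab$subclass == "M_VLDL_P", ]
  others <- tab[tab$subclass != "M_VLDL_P", ]
  expect_gt(abs(coupled$rho_mean), 0.3)
  expect_true(all(others$ci_low <= 0 & others$ci_high >= 0))
})
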