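# Shared fixtures built in code: tiny hand-written cohorts and fast
# sampler settings for replicate studies.

tinySubjects <- function(n_treated = 2, n_placebo = 2) {
  n <- n_treated + n_placebo
  data.frame(subject_id = sprintf("P%02d", seq_len(n)),
             arm = rep(c(1L, 0L), c(n_treated, n_placebo)),
             statin = rep_len(c(1L, 0L), n),
             ezetimibe = rep_len(c(0L, 1L), n),
             stringsAsFactors = FALSE)
}

tinyMeasurements <- function(subjects, metabolites = c("m1", "m2", "m3"),
                             value = 1.5) {
  g <- expand.grid(subject_id = subjects$subject_id,
                   visit = c("baseline", "week16"),
                   metabolite_id = metabolites,
                   stringsAsFactors = FALSE)
  g$concentration <- value + seq_len(nrow(g)) / 100
  g$status <- "observed"
  g
}

# minimal single-metabolite trial config for fast treatment-model replicates
lpaOnlyConfig <- function(seed, effect = log(0.83), n_treated = 16,
                          n_placebo = 14, qc = 0) {
  syntheticConfig(
    n_treated, n_placebo,
    metaboliteSpec("Lp_a", baseline_log_mean = log(230),
                   baseline_log_sd = 0.4, treatment_log_effect = effect,
                   residual_log_sd = 0.152),
    qc_missing_prob = qc, seed = seed)
}

# coupled-pair-only config for fast multilevel replicates
pairOnlyConfig <- function(seed, n_treated, rho = -0.5) {
  sds <- c(0.40, 0.10, 0.40, 0.35)
  R <- diag(4); R[1, 4] <- R[4, 1] <- rho
  sigma_subj <- diag(sds) %*% R %*% diag(sds)
  res <- diag(c(0.08, 0.12)) %*% matrix(c(1, 0.2, 0.2, 1), 2) %*%
    diag(c(0.08, 0.12))
  mets <- rbind(
    metaboliteSpec("Lp_a", log(230), 0.4),
    metaboliteSpec("M_VLDL_P", log(5.2), 0.4))
  syntheticConfig(n_treated, 1, mets,
                  pair = list(lpa_id = "Lp_a", subclass_id = "M_VLDL_P",
                              means = c(log(230), log(0.83), log(5.2), log(0.5)),
                              sigma_subj = sigma_subj, residual_sigma = res),
                  seed = seed)
}

fastSampler <- function(seed, chains = 2, iterations = 1500, warmup = 500) {
  samplerSettings(chains = chains, iterations = iterations, warmup = warmup,
                  adapt = 400, seed = seed)
}

# the hierarchical bivariate model needs more Gibbs iterations per
# effective draw than the regression
mlSampler <- function(seed, chains = 2, iterations = 4000, warmup = 1000) {
  samplerSettings(chains = chains, iterations = iterations, warmup = warmup,
                  adapt = 500, seed = seed)
}
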