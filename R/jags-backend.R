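## Thin internal layer over rjags: deterministic per-chain seeding,
## adaptation/warmup/sampling phases, and shared convergence diagnostics.

.chainSeeds <- function(seed, chains) {
  base <- (abs(as.integer(seed)) %% 2146483L) * 1000L
  base + seq_len(chains)
}

#' @noRd
.runJags <- function(model_string, data, monitors, settings, extra_inits = NULL) {
  seeds <- .chainSeeds(settings@seed, settings@chains)
  inits <- lapply(seq_len(settings@chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seeds[ch])
    if (!is.null(extra_inits)) ini <- c(ini, extra_inits)
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = settings@chains,
                          n.adapt = settings@adapt, quiet = TRUE)
  if (settings@warmup > 0L)
    stats::update(jm, n.iter = settings@warmup, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors,
                      n.iter = settings@iterations - settings@warmup,
                      progress.bar = "none")
}

## R-hat (potential scale reduction) and minimum ESS over a set of
## parameters; R-hat is NA with a single chain.
.mcmcDiagnostics <- function(samples, pars) {
  pars <- intersect(pars, coda::varnames(samples))
  sub <- samples[, pars, drop = FALSE]
  rhat <- NA_real_
  if (length(samples) > 1L) {
    gd <- try(coda::gelman.diag(sub, multivariate = FALSE, autoburnin = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- max(gd$psrf[, 1], na.rm = TRUE)
  }
  ess <- min(coda::effectiveSize(sub))
  flag <- if (!is.na(rhat) && rhat > 1.01) "warn_convergence" else "ok"
  list(rhat_max = rhat, ess_min = ess, flag = flag)
}

## pooled draws of one monitored scalar across chains
.drawsOf <- function(samples, par) {
  unlist(lapply(samples, function(ch) as.numeric(ch[, par])))
}
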