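## Posterior summarization shared by both models.

#' Construct sampler settings
#'
#' Defaults follow the analysis convention for these models: four Markov
#' chains of 2000 iterations each, the first 1000 discarded as warmup,
#' preceded by 500 adaptation iterations.
#'
#' @param chains number of chains.
#' @param iterations total iterations per chain.
#' @param warmup discarded iterations per chain.
#' @param adapt adaptation iterations.
#' @param seed master seed (per-chain seeds are derived deterministically).
#' @param backend backend identifier (only \code{"jags"} is available).
#' @return a \code{\linkS4class{SamplerSettings}}.
#' @export
samplerSettings <- function(chains = 4, iterations = 2000, warmup = 1000,
                            adapt = 500, seed = 1L, backend = "jags") {
  new("SamplerSettings", chains = as.integer(chains),
      iterations = as.integer(iterations), warmup = as.integer(warmup),
      adapt = as.integer(adapt), seed = as.integer(seed), backend = backend)
}

.newSummary <- function(mean, ci, rhat = NA_real_, ess = NA_real_,
                        flag = "ok") {
  new("PosteriorSummary", mean = mean, ci_low = unname(ci[1]),
      ci_high = unname(ci[2]), rhat_max = rhat, ess_min = ess,
      n_divergent = 0L, flag = flag)
}

#' @rdname summarizeDraws
#' @export
setMethod("summarizeDraws", "numeric", function(x, ...) {
  if (length(x) < 100L)
    stop("need at least 100 draws for a stable summary")
  .newSummary(mean(x), quantile(x, c(0.025, 0.975), type = 7))
})

#' @rdname summarizeDraws
#' @export
setMethod("summarizeDraws", "mcmc.list", function(x, ...) {
  if (coda::nvar(x) != 1L)
    stop("supply an mcmc.list with a single monitored variable")
  if (is.null(coda::varnames(x)))
    x <- coda::mcmc.list(lapply(x, function(ch)
      coda::mcmc(matrix(as.numeric(ch), ncol = 1,
                        dimnames = list(NULL, "par")),
                 start = stats::start(ch), thin = coda::thin(ch))))
  draws <- unlist(lapply(x, as.numeric))
  if (length(draws) < 100L)
    stop("need at least 100 draws for a stable summary")
  d <- .mcmcDiagnostics(x, coda::varnames(x))
  .newSummary(mean(draws), quantile(draws, c(0.025, 0.975), type = 7),
              rhat = d$rhat_max, ess = d$ess_min, flag = d$flag)
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: %.4g [%.4g, %.4g]", object@mean,
              object@ci_low, object@ci_high))
  if (!is.na(object@rhat_max))
    cat(sprintf("  (Rhat %.3f, ESS %.0f)", object@rhat_max, object@ess_min))
  cat(sprintf("  [%s]\n", object@flag))
})

#' Coerce a posterior summary (or list of them) to a data.frame
#'
#' @param x a \code{\linkS4class{PosteriorSummary}}.
#' @param row.names,optional,... passed through (unused).
#' @return one-row data.frame with columns \code{mean}, \code{ci_low},
#'   \code{ci_high}, \code{rhat_max}, \code{ess_min}, \code{n_divergent},
#'   \code{flag}.
#' @export
as.data.frame.PosteriorSummary <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(mean = x@mean, ci_low = x@ci_low, ci_high = x@ci_high,
             rhat_max = x@rhat_max, ess_min = x@ess_min,
             n_divergent = x@n_divergent, flag = x@flag,
             stringsAsFactors = FALSE)
}
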