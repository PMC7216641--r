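#' Accessors for cohort and fit objects
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return \code{subjects} and \code{measurements} return the corresponding
#'   data.frame; \code{catalog} the \code{\linkS4class{SubclassCatalog}};
#'   \code{truthData} the hidden pre-missingness table of a synthetic
#'   cohort; \code{posteriorDraws} a matrix of posterior draws.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))

#' @rdname accessors
#' @export
setGeneric("truthData", function(x) standardGeneric("truthData"))

#' @rdname accessors
#' @param pars optional character vector of parameter names to extract.
#' @export
setGeneric("posteriorDraws", function(x, pars = NULL, ...)
  standardGeneric("posteriorDraws"))

#' Posterior percent change implied by a log-scale treatment coefficient
#'
#' @param x a \code{\linkS4class{TreatmentEffectFit}} or a numeric vector of
#'   posterior draws of a log-scale coefficient.
#' @param ... further arguments for methods.
#' @return a \code{\linkS4class{PosteriorSummary}} of the per-draw
#'   reduction \eqn{100\,(1 - e^{\beta})} (positive = reduction).
#' @export
setGeneric("percentChange", function(x, ...) standardGeneric("percentChange"))

#' Posterior correlation between baseline Lp(a) and subclass treatment effect
#'
#' @param x a \code{\linkS4class{MultilevelFit}} or a 4x4xN array of
#'   subject-level covariance draws.
#' @param ... further arguments for methods.
#' @return a \code{\linkS4class{PosteriorSummary}} of the per-draw
#'   correlation \eqn{\rho = \Sigma_{14} / \sqrt{\Sigma_{11}\Sigma_{44}}}.
#' @export
setGeneric("baselineEffectCorrelation", function(x, ...)
  standardGeneric("baselineEffectCorrelation"))

#' Summarize posterior draws
#'
#' Posterior mean and equal-tailed 95\% credible interval (2.5th/97.5th
#' percentiles with linear interpolation), with R-hat and effective sample
#' size attached when per-chain structure is supplied.
#'
#' @param x numeric vector of draws (>= 100) or a \code{coda::mcmc.list}
#'   with a single monitored variable.
#' @param ... further arguments for methods.
#' @return a \code{\linkS4class{PosteriorSummary}}.
#' @export
setGeneric("summarizeDraws", function(x, ...) standardGeneric("summarizeDraws"))
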