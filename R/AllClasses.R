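## Central S4 classes. Validity methods enforce the structural invariants
## that the fitting code relies on, so downstream functions can assume a
## well-formed object.

setOldClass("mcmc.list")

.VISITS <- c("baseline", "week16")
.STATUSES <- c("observed", "below_lod", "qc_rejected")
.LIPO_CLASSES <- c("VLDL", "IDL", "LDL", "HDL")

#' Catalog of NMR lipoprotein subclasses
#'
#' Ordered reference list of lipoprotein subclasses resolved by the NMR
#' platform: short code, lipoprotein class, size label and average particle
#' diameter (nm). The ordering is canonical and used for figures and
#' result tables. Use \code{\link{nightingaleCatalog}} for the standard
#' 14-subclass panel.
#'
#' @slot entries data.frame with columns \code{subclass_id},
#'   \code{class} (one of VLDL, IDL, LDL, HDL), \code{size_label},
#'   \code{diameter_nm}.
#' @export
setClass("SubclassCatalog", representation(entries = "data.frame"))

setValidity("SubclassCatalog", function(object) {
  e <- object@entries
  need <- c("subclass_id", "class", "size_label", "diameter_nm")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return(TRUE)
  if (anyDuplicated(e$subclass_id)) return("duplicate subclass_id")
  if (!all(e$class %in% .LIPO_CLASSES))
    return("class must be one of VLDL, IDL, LDL, HDL")
  if (!is.numeric(e$diameter_nm) || any(e$diameter_nm <= 0))
    return("diameter_nm must be positive")
  for (cl in unique(e$class)) {
    d <- e$diameter_nm[e$class == cl]
    if (length(d) > 1L && any(diff(d) >= 0))
      return(sprintf("diameters must be strictly decreasing within class %s", cl))
  }
  TRUE
})

#' Subject-by-visit metabolomics cohort
#'
#' Container for a two-visit trial cohort: a subject covariate table, a
#' long-format measurement table with per-record status codes, and the
#' subclass catalog that fixes reporting order. Measurements carry one of
#' three statuses: \code{observed} (positive concentration present),
#' \code{below_lod} (interval-censored below the limit of detection,
#' concentration absent) or \code{qc_rejected} (missing at random,
#' concentration absent).
#'
#' A hidden \code{truth} slot may carry the pre-missingness values of a
#' synthetic cohort for recovery testing; it is excluded from serialization
#' by default (see \code{\link{writeCohort}}).
#'
#' @slot subjects data.frame with columns \code{subject_id}, \code{arm}
#'   (1 = active treatment, 0 = placebo), \code{statin}, \code{ezetimibe}
#'   (0/1) and optional demographics.
#' @slot measurements data.frame with columns \code{subject_id},
#'   \code{visit} (\code{baseline}/\code{week16}), \code{metabolite_id},
#'   \code{concentration}, \code{status}.
#' @slot catalog a \code{\linkS4class{SubclassCatalog}}.
#' @slot truth data.frame; hidden pre-missingness measurement table
#'   (possibly empty).
#' @export
setClass("CohortDataset", representation(
  subjects = "data.frame",
  measurements = "data.frame",
  catalog = "SubclassCatalog",
  truth = "data.frame"
))

setValidity("CohortDataset", function(object) {
  s <- object@subjects
  m <- object@measurements
  need_s <- c("subject_id", "arm", "statin", "ezetimibe")
  if (!all(need_s %in% names(s)))
    return(paste("subjects must have columns:", paste(need_s, collapse = ", ")))
  if (anyDuplicated(s$subject_id)) return("duplicate subject_id")
  for (v in c("arm", "statin", "ezetimibe"))
    if (!all(s[[v]] %in% c(0, 1)))
      return(sprintf("%s must be binary 0/1", v))
  need_m <- c("subject_id", "visit", "metabolite_id", "concentration", "status")
  if (!all(need_m %in% names(m)))
    return(paste("measurements must have columns:", paste(need_m, collapse = ", ")))
  if (nrow(m) > 0L) {
    if (!all(m$visit %in% .VISITS))
      return("visit must be 'baseline' or 'week16'")
    if (!all(m$status %in% .STATUSES))
      return("status must be observed, below_lod or qc_rejected")
    if (anyDuplicated(m[, c("subject_id", "visit", "metabolite_id")]))
      return("duplicate (subject_id, visit, metabolite_id) record")
    if (!all(m$subject_id %in% s$subject_id))
      return("measurement subject_id not present in subjects")
    obs <- m$status == "observed"
    if (any(is.na(m$concentration[obs])))
      return("observed records must have a concentration")
    if (any(m$concentration[obs] <= 0))
      return("observed concentrations must be strictly positive (zero is below_lod)")
    if (any(!is.na(m$concentration[!obs])))
      return("non-observed records must not carry a concentration")
    both <- tapply(m$visit, m$subject_id, function(v) all(.VISITS %in% v))
    if (!all(unlist(both)))
      return("every subject with measurements must have records at both visits")
  }
  TRUE
})

#' MCMC sampler settings
#'
#' Run-length configuration shared by all model fits. \code{iterations} is
#' the total per-chain iteration count of which the first \code{warmup} are
#' discarded; \code{adapt} is the JAGS adaptation phase run before warmup.
#'
#' @slot chains integer, number of Markov chains.
#' @slot iterations integer, total iterations per chain.
#' @slot warmup integer, discarded burn-in iterations per chain.
#' @slot adapt integer, adaptation iterations.
#' @slot seed integer, master seed; per-chain RNG seeds are derived from it.
#' @slot backend character, sampler backend identifier.
#' @export
setClass("SamplerSettings", representation(
  chains = "integer", iterations = "integer", warmup = "integer",
  adapt = "integer", seed = "integer", backend = "character"
))

setValidity("SamplerSettings", function(object) {
  if (object@chains < 1L) return("chains must be >= 1")
  if (object@warmup < 0L || object@warmup >= object@iterations)
    return("warmup must be in [0, iterations)")
  if (object@adapt < 0L) return("adapt must be >= 0")
  TRUE
})

#' Posterior summary of a scalar quantity
#'
#' Posterior mean with an equal-tailed 95\% credible interval (2.5th and
#' 97.5th percentiles, linear interpolation) plus convergence diagnostics
#' where chain structure was available. \code{n_divergent} is retained for
#' schema compatibility with Hamiltonian samplers and is always 0 for the
#' Gibbs backend.
#'
#' @slot mean numeric posterior mean.
#' @slot ci_low,ci_high numeric, equal-tailed 95\% interval bounds.
#' @slot rhat_max numeric, largest potential-scale-reduction factor
#'   (NA when a single chain was supplied).
#' @slot ess_min numeric, smallest effective sample size.
#' @slot n_divergent integer, divergent transitions (always 0 here).
#' @slot flag character, one of \code{ok}, \code{warn_convergence},
#'   \code{uninformative}.
#' @export
setClass("PosteriorSummary", representation(
  mean = "numeric", ci_low = "numeric", ci_high = "numeric",
  rhat_max = "numeric", ess_min = "numeric", n_divergent = "integer",
  flag = "character"
))

setValidity("PosteriorSummary", function(object) {
  if (object@ci_low > object@ci_high) return("ci_low must be <= ci_high")
  if (!is.na(object@rhat_max) && object@rhat_max < 0.99)
    return("rhat_max must be >= 1 (tolerance 0.99)")
  if (!object@flag %in% c("ok", "warn_convergence", "uninformative"))
    return("invalid flag")
  TRUE
})

#' Inputs to the lognormal treatment-effect regression
#'
#' Per-subject design vectors for one metabolite: week-16 outcome with
#' status codes, standardized baseline, treatment / statin / ezetimibe
#' indicators, and the censoring ceiling (the minimal observed
#' concentration of the metabolite).
#'
#' @slot analyte character metabolite id.
#' @slot y numeric week-16 concentrations (NA when not observed).
#' @slot status character status per outcome.
#' @slot x numeric standardized baseline concentrations (mean 0, SD 1 over
#'   observed entries; missing baselines mean-imputed at 0).
#' @slot treatment,statin,ezetimibe numeric 0/1 indicator vectors.
#' @slot lod_floor numeric, minimal observed concentration (upper bound for
#'   censored imputations).
#' @slot n_baseline_missing integer, baselines that were mean-imputed.
#' @export
setClass("TreatmentRegressionInputs", representation(
  analyte = "character", y = "numeric", status = "character",
  x = "numeric", treatment = "numeric", statin = "numeric",
  ezetimibe = "numeric", lod_floor = "numeric",
  n_baseline_missing = "integer"
))

setValidity("TreatmentRegressionInputs", function(object) {
  n <- length(object@y)
  lens <- c(length(object@status), length(object@x), length(object@treatment),
            length(object@statin), length(object@ezetimibe))
  if (any(lens != n)) return("all design vectors must have equal length")
  if (!all(object@status %in% .STATUSES)) return("invalid status")
  if (!all(object@treatment %in% c(0, 1))) return("treatment must be 0/1")
  TRUE
})

#' Fitted lognormal treatment-effect regression
#'
#' Posterior draws (a \code{coda::mcmc.list}) for the regression
#' coefficients, the log-scale residual SD and one imputation parameter per
#' missing outcome, together with sampler diagnostics.
#'
#' @slot analyte character metabolite id.
#' @slot samples mcmc.list of posterior draws.
#' @slot coef_names character, monitored coefficient names.
#' @slot imputation_names character, monitored imputation node names
#'   (log-concentration scale).
#' @slot censored_names character, subset of imputation nodes that are
#'   interval-censored below the LOD ceiling.
#' @slot adjusted logical, whether statin/ezetimibe terms were requested.
#' @slot dropped character, adjustment terms dropped because the indicator
#'   was constant in the data.
#' @slot lod_floor numeric censoring ceiling (concentration scale).
#' @slot n_below_lod,n_mar integer missing-data counts.
#' @slot diagnostics list with \code{rhat_max}, \code{ess_min}, \code{flag}.
#' @slot settings the \code{\linkS4class{SamplerSettings}} used.
#' @export
setClass("TreatmentEffectFit", representation(
  analyte = "character", samples = "ANY", coef_names = "character",
  imputation_names = "character", censored_names = "character",
  adjusted = "logical", dropped = "character", lod_floor = "numeric",
  n_below_lod = "integer", n_mar = "integer", diagnostics = "list",
  settings = "SamplerSettings"
))

#' Fitted multilevel bivariate lognormal model
#'
#' Posterior draws for the two-visit Lp(a)/subclass hierarchy in treated
#' subjects: hyper-means, the 4x4 subject-level covariance, per-subject
#' effect quadruples, the 2x2 residual parameters, and the derived
#' correlation \eqn{\rho} between baseline log-Lp(a) and the subject-level
#' subclass treatment effect.
#'
#' @slot subclass character subclass id.
#' @slot lpa_id character metabolite id used as Lp(a).
#' @slot samples mcmc.list of posterior draws.
#' @slot subject_ids character, treated subjects in model order.
#' @slot n_below_lod integer, censored subclass observations.
#' @slot prior_rho_ci numeric length-2, equal-tailed 95\% interval of the
#'   prior on \eqn{\rho} (Monte Carlo).
#' @slot uninformative logical, TRUE when the posterior \eqn{\rho} interval
#'   is at least 90\% as wide as the prior interval.
#' @slot diagnostics list with \code{rhat_max}, \code{ess_min}, \code{flag}.
#' @slot notes character, data-handling notices (latent samples etc).
#' @slot settings the \code{\linkS4class{SamplerSettings}} used.
#' @export
setClass("MultilevelFit", representation(
  subclass = "character", lpa_id = "character", samples = "ANY",
  subject_ids = "character", n_below_lod = "integer",
  prior_rho_ci = "numeric", uninformative = "logical",
  diagnostics = "list", notes = "character", settings = "SamplerSettings"
))

#' Generative specification for synthetic cohorts
#'
#' Full description of the synthetic trial: arm sizes, per-metabolite
#' lognormal baselines and multiplicative effects, the coupled
#' Lp(a)/subclass pair with its 4x4 subject-effect covariance and 2x2
#' residual covariance, missingness mechanisms and the master seed.
#'
#' @slot n_treated,n_placebo integer arm sizes.
#' @slot metabolites data.frame with columns \code{metabolite_id},
#'   \code{baseline_log_mean}, \code{baseline_log_sd},
#'   \code{treatment_log_effect}, \code{statin_log_effect},
#'   \code{ezetimibe_log_effect}, \code{residual_log_sd}, \code{lod}.
#' @slot statin_prob,ezetimibe_prob numeric in [0,1].
#' @slot qc_missing_prob numeric in [0,1], per-record QC-rejection rate.
#' @slot carryover numeric, regression-to-the-mean coefficient linking the
#'   week-16 log-mean to the subject's baseline deviation (default 0.8).
#' @slot pair list describing the coupled pair: \code{lpa_id},
#'   \code{subclass_id}, \code{means} (length-4 \eqn{\theta_L, \gamma_L,
#'   \theta_y, \gamma_y}), \code{sigma_subj} (4x4 SPD), \code{residual_sigma}
#'   (2x2 SPD). May be empty (no coupled pair).
#' @slot seed integer master seed; independent sub-streams are derived for
#'   covariates, concentrations, subject effects and missingness.
#' @export
setClass("SyntheticConfig", representation(
  n_treated = "integer", n_placebo = "integer", metabolites = "data.frame",
  statin_prob = "numeric", ezetimibe_prob = "numeric",
  qc_missing_prob = "numeric", carryover = "numeric", pair = "list",
  seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  if (object@n_treated < 1L || object@n_placebo < 1L)
    return("arm sizes must be >= 1")
  m <- object@metabolites
  need <- c("metabolite_id", "baseline_log_mean", "baseline_log_sd",
            "treatment_log_effect", "statin_log_effect",
            "ezetimibe_log_effect", "residual_log_sd", "lod")
  if (!all(need %in% names(m)))
    return(paste("metabolites must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$metabolite_id)) return("duplicate metabolite_id")
  if (any(m$lod < 0)) return("lod must be non-negative")
  for (p in c("statin_prob", "ezetimibe_prob", "qc_missing_prob")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) return(sprintf("%s must be in [0,1]", p))
  }
  if (length(object@pair)) {
    pr <- object@pair
    need_p <- c("lpa_id", "subclass_id", "means", "sigma_subj", "residual_sigma")
    if (!all(need_p %in% names(pr)))
      return(paste("pair must have elements:", paste(need_p, collapse = ", ")))
    if (length(pr$means) != 4L) return("pair$means must have length 4")
    for (nm in c("sigma_subj", "residual_sigma")) {
      S <- pr[[nm]]
      d <- if (nm == "sigma_subj") 4L else 2L
      if (!is.matrix(S) || !all(dim(S) == d)) return(sprintf("pair$%s must be %dx%d", nm, d, d))
      if (max(abs(S - t(S))) > 1e-8) return(sprintf("pair$%s must be symmetric", nm))
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) return(sprintf("pair$%s must be positive definite", nm))
    }
    if (!all(c(pr$lpa_id, pr$subclass_id) %in% m$metabolite_id))
      return("pair ids must appear in the metabolites table")
  }
  TRUE
})
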