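## Cohort container, CSV I/O and small lipid utilities.

#' Construct a cohort dataset
#'
#' @param subjects data.frame of subject covariates (see
#'   \code{\linkS4class{CohortDataset}}).
#' @param measurements long-format data.frame of measurements.
#' @param catalog a \code{\linkS4class{SubclassCatalog}}; defaults to the
#'   Nightingale 14-subclass panel.
#' @param truth optional hidden pre-missingness measurement table.
#' @return a validated \code{\linkS4class{CohortDataset}}.
#' @export
CohortDataset <- function(subjects, measurements,
                          catalog = nightingaleCatalog(),
                          truth = data.frame()) {
  subjects <- as.data.frame(subjects)
  measurements <- as.data.frame(measurements)
  if (nrow(measurements) && !"concentration" %in% names(measurements))
    measurements$concentration <- NA_real_
  measurements$concentration <- as.numeric(measurements$concentration)
  if (nrow(measurements) && any(!is.na(measurements$concentration) &
                                measurements$concentration < 0))
    stop("negative concentration is invalid")
  new("CohortDataset", subjects = subjects, measurements = measurements,
      catalog = catalog, truth = as.data.frame(truth))
}

#' @rdname accessors
#' @export
setMethod("subjects", "CohortDataset", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("measurements", "CohortDataset", function(x) x@measurements)

#' @rdname accessors
#' @export
setMethod("catalog", "CohortDataset", function(x) x@catalog)

#' @rdname accessors
#' @export
setMethod("truthData", "CohortDataset", function(x) x@truth)

setMethod("show", "CohortDataset", function(object) {
  m <- object@measurements
  cat(sprintf("CohortDataset: %d subjects (%d treated / %d placebo), %d measurement records\n",
              nrow(object@subjects), sum(object@subjects$arm == 1),
              sum(object@subjects$arm == 0), nrow(m)))
  if (nrow(m)) {
    st <- table(factor(m$status, levels = .STATUSES))
    cat(sprintf("  %d metabolites; status: %s\n",
                length(unique(m$metabolite_id)),
                paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  }
  if (nrow(object@truth))
    cat("  (hidden truth channel present)\n")
})

#' Read a cohort from long-format CSVs
#'
#' Reads the canonical pair of CSV files: a long-format measurement table
#' (\code{subject_id, visit, metabolite_id, concentration, status}) and a
#' subject covariate table (\code{subject_id, arm, statin, ezetimibe},
#' optional demographics). Statuses other than \code{observed} must carry
#' an empty concentration field; an absent status column is inferred
#' (missing concentration = \code{qc_rejected}, zero = \code{below_lod}).
#'
#' @param measurements_path CSV path for the measurement table.
#' @param subjects_path CSV path for the subject table.
#' @param catalog a \code{\linkS4class{SubclassCatalog}}.
#' @return a validated \code{\linkS4class{CohortDataset}}. Observed values
#'   round-trip bit-identically through \code{\link{writeCohort}}.
#' @export
readCohort <- function(measurements_path, subjects_path,
                       catalog = nightingaleCatalog()) {
  m <- read.csv(measurements_path, stringsAsFactors = FALSE,
                colClasses = c(concentration = "character"))
  s <- read.csv(subjects_path, stringsAsFactors = FALSE)
  conc <- suppressWarnings(as.numeric(m$concentration))
  bad <- !is.na(m$concentration) & m$concentration != "" & is.na(conc)
  if (any(bad)) stop("non-numeric concentration value")
  m$concentration <- conc
  if (!"status" %in% names(m)) {
    m$status <- ifelse(is.na(m$concentration), "qc_rejected",
                       ifelse(m$concentration == 0, "below_lod", "observed"))
    m$concentration[m$status != "observed"] <- NA_real_
  }
  if (nrow(m) && !all(m$visit %in% .VISITS))
    stop("unknown visit label: ",
         paste(setdiff(unique(m$visit), .VISITS), collapse = ", "))
  if (anyDuplicated(m[, c("subject_id", "visit", "metabolite_id")]))
    stop("duplicate (subject_id, visit, metabolite_id) record")
  CohortDataset(s, m, catalog = catalog)
}

#' Read a wide-format measurement table
#'
#' Convenience reader for a wide table (\code{subject_id, visit}, one
#' column per metabolite) that is normalized to the canonical long format:
#' positive values become \code{observed}, zeros \code{below_lod} and empty
#' cells \code{qc_rejected}.
#'
#' @param measurements_path wide-format CSV path.
#' @param subjects_path subject covariate CSV path.
#' @param catalog a \code{\linkS4class{SubclassCatalog}}.
#' @return a validated \code{\linkS4class{CohortDataset}}.
#' @export
readCohortWide <- function(measurements_path, subjects_path,
                           catalog = nightingaleCatalog()) {
  w <- read.csv(measurements_path, stringsAsFactors = FALSE)
  s <- read.csv(subjects_path, stringsAsFactors = FALSE)
  mets <- setdiff(names(w), c("subject_id", "visit"))
  long <- do.call(rbind, lapply(mets, function(met) {
    v <- w[[met]]
    data.frame(subject_id = w$subject_id, visit = w$visit,
               metabolite_id = met, concentration = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  long$status <- ifelse(is.na(long$concentration), "qc_rejected",
                        ifelse(long$concentration == 0, "below_lod", "observed"))
  long$concentration[long$status != "observed"] <- NA_real_
  if (!all(long$visit %in% .VISITS))
    stop("unknown visit label")
  CohortDataset(s, long, catalog = catalog)
}

#' Write a cohort to the canonical CSV pair
#'
#' Observed concentrations are serialized with 17 significant digits so
#' that a read/write round trip is bit-identical. The hidden truth channel
#' of a synthetic cohort is not written unless \code{includeTruth = TRUE}
#' (a third file with suffix \code{.truth.csv}).
#'
#' @param dataset a \code{\linkS4class{CohortDataset}}.
#' @param measurements_path,subjects_path output CSV paths.
#' @param includeTruth logical, also write the truth channel.
#' @return invisibly, the measurement path.
#' @export
writeCohort <- function(dataset, measurements_path, subjects_path,
                        includeTruth = FALSE) {
  stopifnot(is(dataset, "CohortDataset"))
  fmt <- function(m) {
    m$concentration <- ifelse(is.na(m$concentration), "",
                              sprintf("%.17g", m$concentration))
    m
  }
  write.csv(fmt(dataset@measurements), measurements_path,
            row.names = FALSE, quote = FALSE)
  write.csv(dataset@subjects, subjects_path, row.names = FALSE, quote = FALSE)
  if (includeTruth && nrow(dataset@truth))
    write.csv(fmt(dataset@truth), sub("\\.csv$", ".truth.csv", measurements_path),
              row.names = FALSE, quote = FALSE)
  invisible(measurements_path)
}

#' Restrict a cohort to one arm
#'
#' @param dataset a \code{\linkS4class{CohortDataset}}.
#' @param arm 1 (treated) or 0 (placebo).
#' @return the restricted \code{\linkS4class{CohortDataset}}.
#' @export
subsetArm <- function(dataset, arm = 1) {
  stopifnot(is(dataset, "CohortDataset"), arm %in% c(0, 1))
  keep <- dataset@subjects$subject_id[dataset@subjects$arm == arm]
  m <- dataset@measurements[dataset@measurements$subject_id %in% keep, ,
                            drop = FALSE]
  tr <- dataset@truth
  if (nrow(tr)) tr <- tr[tr$subject_id %in% keep, , drop = FALSE]
  CohortDataset(dataset@subjects[dataset@subjects$arm == arm, , drop = FALSE],
                m, catalog = dataset@catalog, truth = tr)
}

## conversion factors between SI and conventional units, per quantity
.UNIT_FACTORS <- list(
  cholesterol = list(op = "*", k = 38.7),   # mmol/L -> mg/dL
  triglycerides = list(op = "*", k = 88.6), # mmol/L -> mg/dL
  lipoprotein_a = list(op = "/", k = 2.5)   # nmol/L -> mg/dL
)

#' Convert lipid concentrations between SI and conventional units
#'
#' Cholesterol mmol/L x 38.7 = mg/dL; triglycerides mmol/L x 88.6 = mg/dL;
#' lipoprotein(a) nmol/L / 2.5 = mg/dL. \code{from_mg_dl} applies the
#' inverse mapping.
#'
#' @param value non-negative concentration(s).
#' @param quantity one of \code{"cholesterol"}, \code{"triglycerides"},
#'   \code{"lipoprotein_a"}.
#' @param direction \code{"to_mg_dl"} or \code{"from_mg_dl"}.
#' @return converted value(s).
#' @examples
#' convertUnits(1, "cholesterol", "to_mg_dl")    # 38.7
#' convertUnits(250, "lipoprotein_a", "to_mg_dl") # 100
#' @export
convertUnits <- function(value, quantity, direction = c("to_mg_dl", "from_mg_dl")) {
  direction <- match.arg(direction)
  if (!quantity %in% names(.UNIT_FACTORS))
    stop("unknown quantity: ", quantity)
  if (any(value < 0)) stop("value must be non-negative")
  f <- .UNIT_FACTORS[[quantity]]
  forward <- identical(f$op, "*")
  if (direction == "from_mg_dl") forward <- !forward
  if (forward) value * f$k else value / f$k
}

#' Friedewald estimate of LDL cholesterol
#'
#' LDL-C = total cholesterol - HDL cholesterol - triglycerides / 2.2, all
#' in mmol/L. Refuses triglycerides above 4.52 mmol/L (400 mg/dL), where
#' the estimate is invalid and ultracentrifugation measurement is required.
#'
#' @param total_chol,hdl_chol,triglycerides concentrations in mmol/L.
#' @return estimated LDL cholesterol in mmol/L.
#' @examples
#' friedewaldLdl(5.2, 1.3, 2.2)  # 2.9
#' @export
friedewaldLdl <- function(total_chol, hdl_chol, triglycerides) {
  if (any(c(total_chol, hdl_chol, triglycerides) < 0))
    stop("inputs must be non-negative")
  if (any(triglycerides > 4.52))
    stop("triglycerides above 4.52 mmol/L: ultracentrifugation required")
  total_chol - hdl_chol - triglycerides / 2.2
}

#' Standardize baseline concentrations to z-scores
#'
#' Centers and scales so the observed entries have mean 0 and sample
#' (n - 1) standard deviation 1; missing entries propagate as NA.
#'
#' @param values numeric vector of baseline concentrations (NA = missing).
#' @return z-score vector of the same length.
#' @examples
#' standardizeBaseline(c(1, 2, 3))  # -1 0 1
#' @export
standardizeBaseline <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L)
    stop("need at least 2 observed values to standardize")
  s <- sd(obs)
  if (s == 0) stop("zero-variance input cannot be standardized")
  (values - mean(obs)) / s
}
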