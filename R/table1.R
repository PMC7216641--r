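## Baseline-characteristics table: descriptive statistics by arm with
## rank-sum tests for continuous variables and Pearson chi-square tests
## (no continuity correction) for categorical ones.

#' Pearson chi-square p-value for a 2x2 table
#'
#' Pearson chi-square statistic without Yates continuity correction,
#' df = 1, upper-tail p-value. The no-correction dialect is what
#' reproduces standard trial baseline tables for small arms.
#'
#' @param a,b,c,d cell counts (rows = arms, columns = trait
#'   present/absent), or a 2x2 matrix as \code{a}.
#' @return the p-value.
#' @examples
#' chiSquareP(7, 9, 7, 7)   # 0.732 (males by arm, 16 vs 14 subjects)
#' @export
chiSquareP <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be non-negative with positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: test undefined")
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 10 observations and
#' there are no ties; otherwise the normal approximation with tie
#' correction (and continuity correction).
#'
#' @param x,y numeric vectors for the two arms.
#' @param method \code{"auto"} (the rule above), \code{"exact"} or
#'   \code{"normal"}.
#' @return the p-value.
#' @examples
#' wilcoxonP(c(1, 2, 3), c(4, 5, 6))  # 0.1, exact enumeration
#' @export
wilcoxonP <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
                  auto = length(x) <= 10 && length(y) <= 10 && !ties,
                  exact = TRUE, normal = FALSE)
  # with ties an exact request falls back to the tie-corrected approximation
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Default variable specification for a baseline table
#'
#' @return data.frame with columns \code{variable}, \code{kind}
#'   (\code{mean_sd}, \code{median_iqr} or \code{count_pct}) and
#'   \code{digits} used by \code{\link{buildTable1}}. Continuous variables
#'   get the rank-sum test, categorical ones the chi-square test.
#' @export
table1Spec <- function() {
  data.frame(
    variable = c("age", "sex_male", "bmi", "smoking", "sbp", "dbp", "cvd",
                 "statin", "ezetimibe"),
    kind = c("mean_sd", "count_pct", "mean_sd", "count_pct", "mean_sd",
             "mean_sd", "count_pct", "count_pct", "count_pct"),
    digits = c(1, 0, 1, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

.fmt <- function(v, digits) formatC(v, format = "f", digits = digits)

## percentages rounded half-up to integers
.pctInt <- function(k, n) floor(100 * k / n + 0.5)

#' Build a baseline-characteristics table
#'
#' Computes per-arm descriptive statistics and between-arm p-values for a
#' set of variables drawn from the subject covariate table or from
#' baseline measurements (a variable named like a metabolite id uses that
#' metabolite's observed baseline concentrations). Kinds: \code{mean_sd}
#' formatted "mean (SD)" with a rank-sum p-value; \code{median_iqr}
#' "median [q1-q3]" (25th/75th percentiles, linear interpolation) with a
#' rank-sum p-value; \code{count_pct} "n (\%)" (percentages rounded
#' half-up) with the no-correction chi-square p-value.
#'
#' @param dataset a \code{\linkS4class{CohortDataset}}.
#' @param spec data.frame with columns \code{variable}, \code{kind} and
#'   optionally \code{digits}; see \code{\link{table1Spec}}.
#' @return data.frame with one row per available variable: formatted
#'   per-arm cells, numeric p-value, test name. Variables absent from the
#'   dataset are skipped with a notice and listed in the
#'   \code{"skipped"} attribute.
#' @export
buildTable1 <- function(dataset, spec = table1Spec()) {
  stopifnot(is(dataset, "CohortDataset"))
  s <- dataset@subjects
  m <- dataset@measurements
  if (!nrow(spec))
    return(structure(data.frame(variable = character(), kind = character(),
                                treated = character(), placebo = character(),
                                p_value = numeric(), test = character(),
                                stringsAsFactors = FALSE),
                     skipped = character()))
  if (!"digits" %in% names(spec)) spec$digits <- 1

  pull <- function(var) {
    if (var %in% names(s)) return(s[[var]])
    b <- m[m$metabolite_id == var & m$visit == "baseline" &
             m$status == "observed", ]
    if (nrow(b)) {
      idx <- match(s$subject_id, b$subject_id)
      return(b$concentration[idx])
    }
    NULL
  }

  skipped <- character()
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    var <- spec$variable[i]; kind <- spec$kind[i]; dg <- spec$digits[i]
    v <- pull(var)
    if (is.null(v)) {
      skipped <- c(skipped, var)
      next
    }
    vt <- v[s$arm == 1]; vp <- v[s$arm == 0]
    if (kind == "count_pct") {
      ct <- c(sum(vt == 1, na.rm = TRUE), sum(vt != 1, na.rm = TRUE),
              sum(vp == 1, na.rm = TRUE), sum(vp != 1, na.rm = TRUE))
      p <- tryCatch(chiSquareP(ct[1], ct[2], ct[3], ct[4]),
                    error = function(e) NA_real_)
      cell <- function(k, n) sprintf("%d (%d)", k, .pctInt(k, n))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, kind = kind,
        treated = cell(ct[1], ct[1] + ct[2]),
        placebo = cell(ct[3], ct[3] + ct[4]),
        p_value = p, test = "chi_square", stringsAsFactors = FALSE)
    } else {
      p <- tryCatch(wilcoxonP(vt[!is.na(vt)], vp[!is.na(vp)]),
                    error = function(e) NA_real_)
      cell <- if (kind == "mean_sd") {
        function(z) sprintf("%s (%s)", .fmt(mean(z, na.rm = TRUE), dg),
                            .fmt(sd(z, na.rm = TRUE), dg))
      } else {
        function(z) {
          q <- quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
          sprintf("%s [%s-%s]", .fmt(q[2], dg), .fmt(q[1], dg), .fmt(q[3], dg))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, kind = kind, treated = cell(vt), placebo = cell(vp),
        p_value = p, test = "wilcoxon", stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message("skipped (not in dataset): ", paste(skipped, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), kind = character(),
               treated = character(), placebo = character(),
               p_value = numeric(), test = character(),
               stringsAsFactors = FALSE)
  structure(out, skipped = skipped)
}
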