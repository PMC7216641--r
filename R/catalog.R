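#' Construct a subclass catalog
#'
#' @param entries data.frame with columns \code{subclass_id}, \code{class},
#'   \code{size_label}, \code{diameter_nm}, ordered as results should be
#'   reported (largest particles first within each class).
#' @return a \code{\linkS4class{SubclassCatalog}}.
#' @seealso \code{\link{nightingaleCatalog}} for the canonical 14-subclass
#'   panel.
#' @export
SubclassCatalog <- function(entries = data.frame(
    subclass_id = character(), class = character(),
    size_label = character(), diameter_nm = numeric())) {
  new("SubclassCatalog", entries = as.data.frame(entries))
}

#' The 14-subclass Nightingale lipoprotein particle catalog
#'
#' Canonical catalog of the 14 NMR-resolved lipoprotein subclasses with
#' their average particle diameters: six VLDL fractions (extremely large,
#' nominal diameter above 75 nm, down to very small at 31.3 nm), IDL
#' (28.6 nm), three LDL fractions (25.5, 23.0, 18.7 nm) and four HDL
#' fractions (14.3, 12.1, 10.9, 8.7 nm). Subclass ids follow the public
#' Nightingale naming for particle concentrations (e.g. \code{M_VLDL_P}).
#' The extremely large VLDL diameter is recorded as the nominal 75 nm
#' lower bound of its size window.
#'
#' @return a \code{\linkS4class{SubclassCatalog}} with exactly 14 entries.
#' @examples
#' cat14 <- nightingaleCatalog()
#' nrow(catalogEntries(cat14))
#' @export
nightingaleCatalog <- function() {
  e <- data.frame(
    subclass_id = c("XXL_VLDL_P", "XL_VLDL_P", "L_VLDL_P", "M_VLDL_P",
                    "S_VLDL_P", "XS_VLDL_P", "IDL_P",
                    "L_LDL_P", "M_LDL_P", "S_LDL_P",
                    "XL_HDL_P", "L_HDL_P", "M_HDL_P", "S_HDL_P"),
    class = c(rep("VLDL", 6), "IDL", rep("LDL", 3), rep("HDL", 4)),
    size_label = c("extremely large VLDL", "very large VLDL", "large VLDL",
                   "medium VLDL", "small VLDL", "very small VLDL", "IDL",
                   "large LDL", "medium LDL", "small LDL",
                   "very large HDL", "large HDL", "medium HDL", "small HDL"),
    diameter_nm = c(75.0, 64.0, 53.6, 44.5, 36.8, 31.3, 28.6,
                    25.5, 23.0, 18.7, 14.3, 12.1, 10.9, 8.7),
    stringsAsFactors = FALSE
  )
  out <- SubclassCatalog(e)
  stopifnot(nrow(out@entries) == 14L)
  out
}

#' @rdname SubclassCatalog
#' @param x a \code{\linkS4class{SubclassCatalog}}.
#' @return \code{catalogEntries} returns the entries data.frame;
#'   \code{subclassIds} the ordered ids.
#' @export
catalogEntries <- function(x) {
  stopifnot(is(x, "SubclassCatalog"))
  x@entries
}

#' @rdname SubclassCatalog
#' @export
subclassIds <- function(x) catalogEntries(x)$subclass_id

#' Write a catalog to CSV (for external plotting order)
#'
#' @param x a \code{\linkS4class{SubclassCatalog}}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeCatalog <- function(x, path) {
  write.csv(catalogEntries(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

setMethod("show", "SubclassCatalog", function(object) {
  e <- object@entries
  cat(sprintf("SubclassCatalog with %d subclasses\n", nrow(e)))
  if (nrow(e)) {
    tab <- table(factor(e$class, levels = .LIPO_CLASSES))
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
    cat("  diameters:", paste(format(e$diameter_nm), collapse = ", "), "nm\n")
  }
})
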