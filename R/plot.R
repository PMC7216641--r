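#' Forest plot of per-analyte treatment effects
#'
#' One row per analyte (catalog order, largest particles on top), a point
#' at the posterior mean percent reduction and a horizontal line spanning
#' the 95\% credible interval, with a dashed reference line at zero. The
#' plot is fully determined by its inputs.
#'
#' @param summaries data.frame as returned by \code{\link{fitPanel}}
#'   (columns \code{analyte}, \code{mean_reduction_pct}, \code{ci_low},
#'   \code{ci_high}); rows with missing estimates are dropped.
#' @param reference a \code{\linkS4class{SubclassCatalog}} fixing row
#'   order; analytes not in the catalog keep their input order at the
#'   bottom.
#' @return a \code{ggplot} object.
#' @export
forestPlot <- function(summaries, reference = nightingaleCatalog()) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  df <- summaries[!is.na(summaries$mean_reduction_pct), , drop = FALSE]
  if (!nrow(df)) stop("no plottable summaries")
  ord <- c(intersect(subclassIds(reference), df$analyte),
           setdiff(df$analyte, subclassIds(reference)))
  df$analyte <- factor(df$analyte, levels = rev(ord))
  df <- df[order(df$analyte), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_reduction_pct,
                                   y = .data$analyte)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey30") +
    ggplot2::geom_point(size = 2.2, shape = 21, fill = "steelblue") +
    ggplot2::labs(x = "Reduction at week 16 (%), posterior mean and 95% CI",
                  y = NULL) +
    ggplot2::theme_minimal(base_size = 11)
}

#' Write a forest plot to PNG (and optionally SVG)
#'
#' @param plot a ggplot object from \code{\link{forestPlot}}.
#' @param path output PNG path.
#' @param svg also write an SVG next to it (requires cairo capability).
#' @param width,height,dpi device geometry.
#' @return invisibly, the PNG path.
#' @export
saveForestPlot <- function(plot, path, svg = FALSE, width = 6, height = 5,
                           dpi = 150) {
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  print(plot)
  grDevices::dev.off()
  if (svg && capabilities("cairo")) {
    grDevices::svg(sub("\\.png$", ".svg", path), width = width, height = height)
    print(plot)
    grDevices::dev.off()
  }
  invisible(path)
}
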