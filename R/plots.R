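#' Diagnostic plots
#'
#' Base-graphics companions to the evaluation outputs: the cyst-area
#' histogram of a set of matches or scenes, the cumulative detected-pair
#' IoU curve, and per-zone cyst-wise metric bars.
#'
#' @param areas cyst areas in um^2.
#' @param breaks histogram breaks passed to \code{hist}.
#' @return invisibly, the plotted object.
#' @name cystwise-plots
NULL

#' @rdname cystwise-plots
#' @export
plotAreaHistogram <- function(areas, breaks = 40) {
  graphics::hist(areas, breaks = breaks, col = "grey80", border = "white",
                 main = "Cyst area distribution", xlab = "area (µm²)")
  graphics::abline(v = stats::median(areas), lty = 2)
  invisible(areas)
}

#' @rdname cystwise-plots
#' @param dist a \code{dtIouDistribution}.
#' @export
plotIouCumulative <- function(dist) {
  if (length(dist$iou) == 0L) stop("no detected pairs to plot")
  graphics::plot(dist$iou, dist$cumulative, type = "s",
                 xlab = "pairwise IoU", ylab = "cumulative fraction",
                 main = "IoU of detected cyst pairs", xlim = c(0, 1),
                 ylim = c(0, 1))
  invisible(dist)
}

#' @rdname cystwise-plots
#' @param zoneTable the \code{zoneTable} of \code{\link{evaluateCatalog}}.
#' @export
plotZoneMetrics <- function(zoneTable) {
  m <- t(as.matrix(zoneTable[, c("IoU_cyst", "Pr_cyst", "Re_cyst")]))
  graphics::barplot(m, beside = TRUE, names.arg = zoneTable$zone,
                    xlab = "size zone", ylab = "metric", ylim = c(0, 1),
                    legend.text = rownames(m),
                    main = "Cyst-wise performance by size zone")
  invisible(zoneTable)
}
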