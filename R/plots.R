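#' @include depth_filters.R de.R
#' @import ggplot2
NULL

#' Plot a window curve with its learned threshold
#'
#' Scatter of window companion statistic against window reference
#' median (log10 axes for the lower-limit mode), with the learned
#' threshold as a vertical red dashed line.
#'
#' @param curve a data.frame from [windowCurve()].
#' @param threshold optional threshold (FPKM) to mark.
#' @param xlab,ylab axis labels.
#' @return a ggplot object.
#' @export
plotWindowCurve <- function(curve, threshold = NULL,
                            xlab = "reference window median FPKM",
                            ylab = NULL) {
  prop <- identical(attr(curve, "statistic"), "proportion")
  if (is.null(ylab))
    ylab <- if (prop) "proportion detected" else "companion window median FPKM"
  p <- ggplot(curve, aes(x = .data$refMedian, y = .data$companion)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = xlab, y = ylab) +
    theme_bw()
  if (!prop) p <- p + scale_x_log10() + scale_y_log10()
  else p <- p + scale_x_log10()
  if (!is.null(threshold) && is.finite(threshold) && threshold > 0)
    p <- p + geom_vline(xintercept = threshold, colour = "red",
                        linetype = "dashed")
  p
}

#' Fold-change dotplot of differential expression results
#'
#' log2 fold change against mean expression (log10 CPM), significant
#' genes in red, with horizontal guide lines at +/- `guideFold`-fold
#' change.
#'
#' @param res a result data.frame from [runDE()].
#' @param meanExpr per-gene mean expression (e.g. mean CPM), aligned
#'   with `res`.
#' @param guideFold fold-change guide lines (default 4).
#' @return a ggplot object.
#' @export
plotDE <- function(res, meanExpr, guideFold = 4) {
  stopifnot(length(meanExpr) == nrow(res))
  df <- data.frame(meanExpr = meanExpr, log2fc = res$log2fc,
                   significant = res$significant)
  ggplot(df, aes(x = .data$meanExpr, y = .data$log2fc)) +
    geom_point(aes(colour = .data$significant), size = 0.6,
               show.legend = FALSE) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    scale_x_log10() +
    geom_hline(yintercept = c(-1, 1) * log2(guideFold),
               colour = "blue") +
    labs(x = "mean expression (CPM)", y = "log2 fold change") +
    theme_bw()
}
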