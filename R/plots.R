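#' Plot a skew profile
#'
#' Draws the GC (red) and TA (blue) skew curves against position (or
#' anchor offset).
#'
#' @param x A `skew_profile`.
#' @param which Skews to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @method plot skew_profile
#' @export
plot.skew_profile <- function(x, which = c("gc", "ta"), ...) {
  pos <- if ("offset" %in% names(x)) x$offset else x$position
  cols <- c(gc = "red", ta = "blue")[which]
  y <- as.matrix(as.data.frame(x)[, paste0(which, "_skew"), drop = FALSE])
  graphics::matplot(pos, y, type = "l", lty = 1, col = cols,
                    xlab = if ("offset" %in% names(x)) "offset (bp)" else "position (bp)",
                    ylab = "skew", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @method plot roc
#' @export
plot.roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false-positive rate",
                 ylab = "true-positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, col = "grey", lty = 2)
  invisible(x)
}
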