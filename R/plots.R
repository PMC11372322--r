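#' Bland-Altman plot
#'
#' Differences against means with the mean difference (solid) and limits of
#' agreement (dashed) drawn, plus the proportional-bias regression line.
#'
#' @param x,y Paired measurements (difference direction `x - y`).
#' @param ba Optional precomputed [bland_altman()] result for the same pairs.
#' @param xlab,ylab,main Plot labels.
#' @return The [bland_altman()] result, invisibly.
#' @export
plot_bland_altman <- function(x, y, ba = bland_altman(x, y),
                              xlab = "Mean of methods (ms)",
                              ylab = "Difference, ECG - PPG (ms)",
                              main = "Bland-Altman") {
  d <- x - y
  m <- (x + y) / 2
  pad <- max(0.1 * max(abs(c(ba$loa_lower, ba$loa_upper, d))), 1e-6)
  graphics::plot(m, d, pch = 19, col = "grey30", xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(d, ba$loa_lower - pad, ba$loa_upper + pad)))
  graphics::abline(h = ba$mean_diff, lwd = 2)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
  if (is.finite(ba$prop_slope_b) && stats::var(m) > 0)
    graphics::abline(stats::lm(d ~ m), col = "red")
  invisible(ba)
}

#' Method scatter plot with line of identity
#'
#' @param x,y Paired measurements (x on the abscissa).
#' @param xlab,ylab,main Plot labels.
#' @return The [pearson_cor()] result, invisibly.
#' @export
plot_method_scatter <- function(x, y, xlab = "ECG (ms)", ylab = "PPG (ms)",
                                main = "Method agreement") {
  lim <- range(c(x, y))
  graphics::plot(x, y, pch = 19, col = "grey30", xlim = lim, ylim = lim,
                 xlab = xlab, ylab = ylab, main = main)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(y ~ x), col = "red")
  invisible(pearson_cor(x, y))
}

#' Write the standard agreement figure pair as PNG files
#'
#' @param x,y Paired measurements (ECG first: differences are `x - y`).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_agreement_plots <- function(x, y, dir, prefix = "agreement") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scatter <- file.path(dir, paste0(prefix, "_scatter.png"))
  ba_file <- file.path(dir, paste0(prefix, "_bland_altman.png"))
  grDevices::png(scatter, width = 700, height = 700)
  plot_method_scatter(x, y)
  grDevices::dev.off()
  grDevices::png(ba_file, width = 700, height = 700)
  plot_bland_altman(x, y)
  grDevices::dev.off()
  invisible(c(scatter, ba_file))
}
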