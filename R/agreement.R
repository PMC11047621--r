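#' Bland-Altman agreement analysis
#'
#' Per-pair differences `y - x` against per-pair means, with the bias
#' (mean difference) and the 95% limits of agreement
#' `bias +/- 1.96 x SD(differences)`.
#'
#' @param x,y paired measurements (x = TNC, y = VNC), n >= 2.
#' @return object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`, and `points` (data.frame of means and differences).
#' @export
bland_altman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 points = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.4g, limits [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, main = "Bland-Altman plot",
                              xlab = "mean of pair",
                              ylab = "difference (VNC - TNC)", ...) {
  plot(x$points$mean, x$points$diff, pch = 16,
       col = grDevices::adjustcolor("steelblue4", 0.6),
       main = main, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, col = "black", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "firebrick",
                   lty = 2, lwd = 1.5)
  invisible(x)
}

#' Paired comparison of one metric between TNC and VNC
#'
#' The full paired-agreement summary for one metric: number of pairs,
#' median of the differences (VNC minus TNC), a two-sided Wilcoxon
#' signed-rank test, the effectiveness of pairing r, and the Bland-Altman
#' bias and limits of agreement. When every difference is zero the test is
#' degenerate and the pair set is reported as identical (`p = NA`).
#'
#' @param x,y paired metric values (x = TNC, y = VNC).
#' @param metric name of the compared metric, for reporting.
#' @return object of class `paired_comparison`.
#' @export
paired_compare <- function(x, y, metric = "metric") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  identical_pairs <- n > 0 && all(y == x)
  wt <- if (identical_pairs) NULL else wilcoxon_signed_rank(x, y)
  r <- tryCatch(pairing_effectiveness(x, y), error = function(e) NA_real_)
  ba <- if (n >= 2) bland_altman(x, y) else NULL
  structure(list(
    metric = metric, n = n,
    median_of_differences = median(y - x),
    test_name = if (identical_pairs) "identical" else "Wilcoxon signed-rank",
    statistic = if (identical_pairs) NA_real_ else wt$statistic,
    p_value = if (identical_pairs) NA_real_ else wt$p_value,
    pairing_r = r,
    bland_altman = ba,
    wilcoxon = wt),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s (n = %d)\n", x$metric, x$n))
  if (x$test_name == "identical") {
    cat("  TNC and VNC values identical; paired test degenerate\n")
  } else {
    cat(sprintf("  median of differences = %.4g, W+ = %g, p = %.4g, r = %.2f\n",
                x$median_of_differences, x$statistic, x$p_value,
                x$pairing_r))
  }
  if (!is.null(x$bland_altman))
    cat(sprintf("  Bland-Altman bias %.4g, limits [%.4g, %.4g]\n",
                x$bland_altman$bias, x$bland_altman$loa_low,
                x$bland_altman$loa_high))
  invisible(x)
}

#' @export
plot.paired_comparison <- function(x, ...) {
  if (is.null(x$bland_altman)) stop("no Bland-Altman component to plot")
  plot(x$bland_altman,
       main = sprintf("Bland-Altman: %s", x$metric), ...)
}
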