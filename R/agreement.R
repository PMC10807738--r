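# Method-agreement statistics: two-way absolute-agreement ICC with F-based
# confidence intervals, Bland-Altman limits of agreement, mean absolute
# error. Used to compare two measurement methods (or two runs) over the
# same radiographs.

#' Two-way absolute-agreement intraclass correlation coefficient
#'
#' Computes the two-way model ICC for absolute agreement from the two-way
#' ANOVA decomposition (between-subject, between-rater and residual mean
#' squares), with the F-distribution confidence interval of McGraw & Wong.
#' Single-measures ICC(A,1) is the default, matching the conventional
#' choice for method comparison of individual radiographs;
#' `measures = "average"` gives ICC(A,k).
#'
#' When the residual and rater mean squares are exactly zero (bit-identical
#' ratings of a nonconstant sample) the ICC is exactly 1 and the interval
#' degenerates to `[1, 1]`; the F formulas would otherwise return NaN.
#' A sample with zero total variance has no defined ICC and is an error.
#'
#' @param x,y paired measurement vectors (same subjects, two raters or
#'   methods), length >= 3.
#' @param conf_level confidence level (default 0.95).
#' @param measures `"single"` (default) or `"average"`.
#' @return list with `icc`, `ci` (lower, upper), `conf_level`, `measures`,
#'   `n`, and the mean squares `ms` (subjects, raters, error).
#' @export
icc_absolute_agreement <- function(x, y, conf_level = 0.95,
                                   measures = c("single", "average")) {
  measures <- match.arg(measures)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 complete pairs", call. = FALSE)
  M <- cbind(x, y)
  k <- 2
  grand <- mean(M)
  sst <- sum((M - grand)^2)
  if (sst <= 0) stop("undefined ICC: zero total variance", call. = FALSE)
  ssb <- k * sum((rowMeans(M) - grand)^2)
  ssc <- n * sum((colMeans(M) - grand)^2)
  sse <- max(0, sst - ssb - ssc)
  msb <- ssb / (n - 1)
  msj <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc1 <- (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n)
  icck <- (msb - mse) / (msb + (msj - mse) * k / n)
  alpha <- 1 - conf_level

  tiny <- .Machine$double.eps * max(msb, 1)
  if (mse <= tiny && msj <= tiny) {
    ci1 <- c(1, 1)
    cik <- c(1, 1)
  } else {
    if (mse <= tiny) {
      # limit of the Satterthwaite degrees of freedom as MSE -> 0
      v <- k - 1
    } else {
      fj <- msj / mse
      vn <- (k - 1) * (n - 1) *
        (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
      vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
        (n * (1 + (k - 1) * icc1) - k * icc1)^2
      v <- vn / vd
    }
    # fractional Satterthwaite df can trip qbeta accuracy warnings on
    # degenerate (e.g. anti-agreeing) samples; the quantiles are still usable
    fu <- suppressWarnings(stats::qf(1 - alpha / 2, n - 1, v))
    fl <- suppressWarnings(stats::qf(1 - alpha / 2, v, n - 1))
    lower <- n * (msb - fu * mse) /
      (fu * (k * msj + (k * n - k - n) * mse) + n * msb)
    upper <- n * (fl * msb - mse) /
      (k * msj + (k * n - k - n) * mse + n * fl * msb)
    ci1 <- c(lower, upper)
    # Spearman-Brown step-up of the single-measures bounds
    cik <- ci1 * k / (1 + ci1 * (k - 1))
  }
  if (measures == "single") {
    list(icc = icc1, ci = ci1, conf_level = conf_level, measures = measures,
         n = n, ms = c(subjects = msb, raters = msj, error = mse))
  } else {
    list(icc = icck, ci = cik, conf_level = conf_level, measures = measures,
         n = n, ms = c(subjects = msb, raters = msj, error = mse))
  }
}

#' Bland-Altman agreement analysis
#'
#' Differences are `x - y`; the limits of agreement are the mean difference
#' plus/minus 1.96 standard deviations of the differences.
#'
#' @param x,y paired measurement vectors, length >= 2.
#' @return list with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `n`,
#'   and the per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       n = n, means = (x + y) / 2, diffs = d)
}

#' Mean absolute error between paired measurements
#'
#' @param x,y paired measurement vectors, length >= 1.
#' @return list with `mae`, `sd_ae`, `n`.
#' @export
mean_absolute_error <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  a <- abs(x - y)
  list(mae = mean(a), sd_ae = if (length(a) > 1) stats::sd(a) else 0,
       n = length(a))
}

#' Full agreement summary for one measurement column
#'
#' Bundles the absolute-agreement ICC with its confidence interval, the
#' Bland-Altman statistics and the mean absolute error into one record.
#'
#' @inheritParams icc_absolute_agreement
#' @return object of class `agreement_summary`.
#' @export
agreement_summary <- function(x, y, conf_level = 0.95,
                              measures = "single") {
  icc <- icc_absolute_agreement(x, y, conf_level, measures)
  ba <- bland_altman(x, y)
  mae <- mean_absolute_error(x, y)
  structure(
    list(icc = icc$icc, icc_ci = icc$ci,
         mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
         loa = c(ba$loa_lower, ba$loa_upper),
         mae = mae$mae, sd_ae = mae$sd_ae, n = ba$n,
         conf_level = conf_level),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d\n", x$n))
  cat(sprintf("  ICC(A,1) = %.3f [%.3f, %.3f]\n", x$icc, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  mean diff = %.4f (SD %.4f), LoA [%.4f, %.4f]\n",
              x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  cat(sprintf("  mean absolute error = %.4f (SD %.4f)\n", x$mae, x$sd_ae))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Means on the horizontal axis, differences on the vertical axis, a green
#' mean-difference line and red 95% limit-of-agreement lines.
#'
#' @param x,y paired measurement vectors.
#' @param xlab,ylab axis labels (include units).
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(x, y, xlab = "mean of methods",
                              ylab = "difference between methods") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ba <- bland_altman(x, y)
  df <- data.frame(m = ba$means, d = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "green4") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
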