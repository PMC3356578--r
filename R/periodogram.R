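#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period `P` on a grid with step equal to the epoch
#' length, the series is truncated to the largest whole number of complete
#' cycles `m`, folded into `K = P / epoch` bins, and the statistic
#' `Qp = m * N * sum_h (xbar_h - xbar)^2 / sum_i (x_i - xbar)^2` (with `N =
#' m * K` epochs used) is referred to the chi-square distribution with
#' `K - 1` degrees of freedom. The significance line is the `1 - alpha`
#' chi-square quantile per period; the periodogram amplitude is
#' `Qp - sig_line` at the peak period (negative when no period reaches
#' significance), the convention of commercial actigraphy software.
#'
#' @param series an [activity_series()] spanning at least
#'   `2 * period_max_h`.
#' @param period_min_h,period_max_h period grid limits, hours.
#' @param alpha significance level for the chi-square line.
#' @return An object of class `chisq_periodogram`: list with `periods_h`,
#'   `qp`, `df`, `sig_line`, `peak_period_h`, `amplitude`, `alpha`.
#' @export
chi_square_periodogram <- function(series, period_min_h = 20,
                                   period_max_h = 28, alpha = 0.05) {
  ep_h <- series$epoch_min / 60
  x <- series$counts
  x[series$gap] <- NA
  n <- length(x)
  if (n * ep_h < 2 * period_max_h)
    stop("series must span at least twice the longest candidate period")
  k_grid <- seq(ceiling(period_min_h / ep_h), floor(period_max_h / ep_h))
  if (length(k_grid) == 0L) stop("empty period grid")
  xbar_all_ok <- sum(!is.na(x)) > 1 &&
    sum((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE) > 0
  if (!xbar_all_ok) stop("zero variance; periodogram undefined")
  res <- vapply(k_grid, function(K) {
    m <- n %/% K
    xx <- x[seq_len(m * K)]
    mat <- matrix(xx, nrow = m, ncol = K, byrow = TRUE)
    xbar_h <- colMeans(mat, na.rm = TRUE)
    xbar <- mean(xx, na.rm = TRUE)
    n_use <- sum(!is.na(xx))
    ss <- sum((xx - xbar)^2, na.rm = TRUE)
    qp <- if (ss > 0) m * n_use * sum((xbar_h - xbar)^2) / ss else 0
    c(qp = qp, df = K - 1)
  }, numeric(2))
  qp <- res["qp", ]
  df <- res["df", ]
  sig <- stats::qchisq(1 - alpha, df)
  peak <- which.max(qp)
  structure(list(periods_h = k_grid * ep_h, qp = qp, df = df,
                 sig_line = sig, peak_period_h = k_grid[peak] * ep_h,
                 amplitude = qp[peak] - sig[peak], alpha = alpha),
            class = "chisq_periodogram")
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat(sprintf(
    "<chisq_periodogram> %d periods in [%g, %g] h, alpha = %g\n",
    length(x$periods_h), min(x$periods_h), max(x$periods_h), x$alpha))
  cat(sprintf("  peak %g h: Qp = %.1f, significance line %.1f, amplitude %.1f\n",
              x$peak_period_h, x$qp[which.max(x$qp)],
              x$sig_line[which.max(x$qp)], x$amplitude))
  invisible(x)
}

#' @export
plot.chisq_periodogram <- function(x, ...) {
  graphics::plot(x$periods_h, x$qp, type = "l", xlab = "period (h)",
                 ylab = expression(Q[p]), ...)
  graphics::lines(x$periods_h, x$sig_line, lty = 2, col = "red")
  graphics::abline(v = x$peak_period_h, lty = 3)
  invisible(x)
}

#' Tidy periodogram table
#'
#' @param x a `chisq_periodogram`.
#' @return data.frame with columns `period_h`, `qp`, `df`, `sig_line`.
#' @export
as.data.frame.chisq_periodogram <- function(x, ...) {
  data.frame(period_h = x$periods_h, qp = x$qp, df = x$df,
             sig_line = x$sig_line)
}
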