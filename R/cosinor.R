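#' Single-component cosinor regression
#'
#' Fits `y = M + beta * cos(2*pi*t/P) + gamma * sin(2*pi*t/P)` by ordinary
#' least squares and reports the standard rhythmometric parameters: mesor
#' `M`, amplitude `A = sqrt(beta^2 + gamma^2)` and acrophase
#' `phi = (P / 2*pi) * atan2(gamma, beta) mod P` (the peak time on the ZT
#' axis). Rhythm detection is the 2-df F test of the zero-amplitude
#' reduction. A constant profile yields amplitude 0 with an
#' undefined-flagged (`NA`) acrophase rather than an error.
#'
#' @param profile a [profile_sample()] (columns `zt_h`, `value`).
#' @param period_h fixed period, hours (default 24).
#' @return An object of class `cosinor_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods. Components:
#'   `mesor`, `amplitude`, `acrophase_h`, `period_h`, `residual_sd`,
#'   `F_stat`, `p_value`, `n`, `lm` (the underlying fit).
#' @export
cosinor_fit <- function(profile, period_h = 24) {
  df <- as.data.frame(profile)
  if (!all(c("zt_h", "value") %in% names(df)))
    stop("profile needs columns zt_h, value")
  tt <- df$zt_h %% period_h
  if (length(unique(round(tt, 9))) < 3L)
    stop("need at least 3 distinct sample times (mod period)")
  w <- 2 * pi / period_h
  X <- data.frame(value = df$value, c1 = cos(w * df$zt_h),
                  s1 = sin(w * df$zt_h))
  fit <- stats::lm(value ~ c1 + s1, data = X)
  if (any(is.na(stats::coef(fit))))
    stop("collinear cosinor design; sample more distinct times")
  beta <- unname(stats::coef(fit)["c1"])
  gamma <- unname(stats::coef(fit)["s1"])
  amp <- sqrt(beta^2 + gamma^2)
  scale <- max(abs(df$value), 1e-12)
  degenerate <- amp < 1e-10 * scale
  acro <- if (degenerate) NA_real_
          else (atan2(gamma, beta) / w) %% period_h
  fit0 <- stats::lm(value ~ 1, data = X)
  an <- stats::anova(fit0, fit)
  structure(list(mesor = unname(stats::coef(fit)[1]),
                 amplitude = if (degenerate) 0 else amp,
                 acrophase_h = acro,
                 acrophase_undefined = degenerate,
                 period_h = period_h,
                 residual_sd = stats::sigma(fit),
                 F_stat = an$F[2], p_value = an$`Pr(>F)`[2],
                 n = nrow(df), lm = fit,
                 group = attr(profile, "group")),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit>%s n = %d, period %g h\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, x$period_h))
  cat(sprintf("  mesor %.4g, amplitude %.4g, acrophase %s\n",
              x$mesor, x$amplitude,
              if (x$acrophase_undefined) "undefined (flat profile)"
              else sprintf("ZT %.2f h", x$acrophase_h)))
  if (is.finite(x$F_stat))
    cat(sprintf("  zero-amplitude test: F = %.3g, p = %.3g\n",
                x$F_stat, x$p_value))
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.cosinor_fit <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase_h = object$acrophase_h)
}

#' @export
predict.cosinor_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  zt <- newdata$zt_h
  w <- 2 * pi / object$period_h
  object$mesor +
    unname(stats::coef(object$lm)["c1"]) * cos(w * zt) +
    unname(stats::coef(object$lm)["s1"]) * sin(w * zt)
}

#' @export
fitted.cosinor_fit <- function(object, ...) stats::fitted(object$lm)

#' @export
residuals.cosinor_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.cosinor_fit <- function(x, profile = NULL, ...) {
  zt <- seq(0, x$period_h, length.out = 193)
  yy <- predict(x, newdata = data.frame(zt_h = zt))
  graphics::plot(zt, yy, type = "l", xlab = "ZT (h)", ylab = "value", ...)
  if (!is.null(profile))
    graphics::points(profile$zt_h, profile$value, pch = 16,
                     col = grDevices::adjustcolor("steelblue", 0.7))
  if (!x$acrophase_undefined)
    graphics::abline(v = x$acrophase_h, lty = 3)
  invisible(x)
}

#' Model-free peak bin of a profile
#'
#' ZT of the maximum across-replicate mean; ties are broken to the earliest
#' ZT and flagged via `attr(, "tie")`. This is the bin-based peak call used
#' for coarse (e.g. 4-h) sampling grids.
#'
#' @param profile a [profile_sample()].
#' @return Peak ZT in hours; attribute `tie` is `TRUE` when the maximum was
#'   tied.
#' @export
peak_bin <- function(profile) {
  df <- as.data.frame(profile)
  if (nrow(df) == 0L) stop("empty profile")
  means <- tapply(df$value, df$zt_h, mean)
  zts <- as.numeric(names(means))
  if (length(zts) < 2L) stop("need at least 2 sampled ZTs")
  o <- order(zts)
  means <- means[o]; zts <- zts[o]
  top <- which(means >= max(means) - 1e-12)
  out <- zts[top[1]]
  attr(out, "tie") <- length(top) > 1L
  out
}

#' Circular phase difference between two cosinor fits
#'
#' `(phi_a - phi_b)` wrapped to `(-P/2, P/2]` hours; negative = group a
#' peaks earlier (is phase advanced) on the ZT axis.
#'
#' @param fit_a,fit_b rhythm-positive [cosinor_fit()]s with equal periods.
#' @return Signed hours.
#' @export
group_phase_difference <- function(fit_a, fit_b) {
  if (fit_a$period_h != fit_b$period_h) stop("periods differ")
  if (fit_a$acrophase_undefined || fit_b$acrophase_undefined ||
      fit_a$amplitude <= 0 || fit_b$amplitude <= 0)
    stop("both fits must be rhythm-positive (non-zero amplitude)")
  p <- fit_a$period_h
  d <- (fit_a$acrophase_h - fit_b$acrophase_h) %% p
  if (d > p / 2) d - p else d
}

#' Two-group comparison
#'
#' Thin wrapper over the standard two-sided tests used for group contrasts:
#' `design = "t"` is the pooled-variance two-sample t test;
#' `design = "anova_planned"` fits a one-way model and reports the planned
#' pairwise contrast (numerically identical to the pooled t for two
#' groups, reported with the ANOVA F as context).
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param design `"t"` or `"anova_planned"`.
#' @return List with `estimate` (mean a - mean b), `ci` (95%), `p`,
#'   `method`, `n`.
#' @export
compare_groups <- function(values_a, values_b,
                           design = c("t", "anova_planned")) {
  design <- match.arg(design)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 values per group")
  if (stats::sd(c(values_a, values_b)) == 0)
    stop("degenerate (zero) variance in both groups")
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  out <- list(estimate = unname(diff(rev(tt$estimate))),
              ci = unname(tt$conf.int), p = tt$p.value,
              method = "two-sample t test (pooled variance)",
              n = c(length(values_a), length(values_b)))
  if (design == "anova_planned") {
    y <- c(values_a, values_b)
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    an <- stats::anova(stats::lm(y ~ g))
    out$method <- "one-way ANOVA, planned pairwise comparison"
    out$F_stat <- an$`F value`[1]
  }
  out
}
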