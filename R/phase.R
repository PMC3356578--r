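#' Detect daily activity onsets
#'
#' Template heuristic: within each day the onset is the first epoch that is
#' itself active (counts at or above the daily mean) at a quiet-to-active
#' transition (previous epoch below the daily mean), whose preceding
#' `quiet_h` window has mean activity below `frac_threshold * (daily mean)`
#' with no epoch bursting above `(daily mean) / frac_threshold`, and whose
#' following `active_h` window has mean activity above the daily mean. The
#' burst guard stops mid-band lulls of fragmented nights from being
#' mistaken for onsets, and the asymmetry between the quiet and active
#' thresholds keeps the rule stable on transition days that carry more than
#' one activity band. Days with no
#' qualifying epoch (including all-zero days) are flagged, never fabricated.
#' All parameters are surfaced because onset rules vary between labs.
#'
#' @param series an [activity_series()] spanning at least one complete day.
#' @param quiet_h length of the preceding quiet window, hours.
#' @param active_h length of the following active window, hours.
#' @param frac_threshold asymmetry fraction in `(0, 1)`.
#' @return An object of class `onset_series`: data.frame with columns `day`,
#'   `onset_min` (minutes from that day's midnight; `NA` when flagged),
#'   `onset_h` (absolute hours) and `flagged`; detection parameters in
#'   `attr(, "params")`.
#' @export
detect_onsets <- function(series, quiet_h = 4, active_h = 1,
                          frac_threshold = 0.5) {
  if (quiet_h <= 0 || active_h <= 0 || frac_threshold <= 0 ||
      frac_threshold >= 1)
    stop("invalid onset-detection parameters")
  if (length(series$counts) < 1L) stop("empty series")
  cd <- complete_day_index(series)
  if (length(cd$days) < 1L) stop("need at least one complete day")
  ep <- series$epoch_min
  q <- as.integer(round(quiet_h * 60 / ep))
  a <- as.integer(round(active_h * 60 / ep))
  x <- series$counts
  cs <- cumsum(c(0, x))
  win_mean <- function(i0, i1) (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
  n <- length(x)
  rows <- lapply(cd$days, function(d) {
    ii <- which(cd$day_of == d)
    m_day <- mean(x[ii])
    onset <- NA_real_
    if (m_day > 0) {
      for (i in ii) {
        if (i - q < 1L || i + a - 1L > n) next
        if (x[i] >= m_day && x[i - 1L] < m_day &&
            win_mean(i - q, i - 1L) < frac_threshold * m_day &&
            max(x[(i - q):(i - 1L)]) < m_day / frac_threshold &&
            win_mean(i, i + a - 1L) > m_day) {
          onset <- epoch_starts(series)[i]
          break
        }
      }
    }
    data.frame(day = d,
               onset_min = if (is.na(onset)) NA_real_
                           else (onset - 24 * d) * 60,
               onset_h = onset,
               flagged = is.na(onset))
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(quiet_h = quiet_h, active_h = active_h,
                              frac_threshold = frac_threshold,
                              epoch_min = ep)
  class(out) <- c("onset_series", "data.frame")
  out
}

#' @export
print.onset_series <- function(x, ...) {
  cat(sprintf("<onset_series> %d day(s), %d flagged\n",
              nrow(x), sum(x$flagged)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

wrap_min <- function(m, period_min = 1440) {
  ((m + period_min / 2) %% period_min) - period_min / 2
}

# shortest-path unwrap of onset minutes across midnight
unwrap_onsets <- function(onset_min) {
  u <- onset_min
  for (k in seq_along(u)[-1])
    u[k] <- u[k - 1] + wrap_min(onset_min[k] - u[k - 1] %% 1440)
  u
}

#' Phase angle of entrainment
#'
#' Mean signed interval between daily activity onset and lights-off over
#' unflagged LD days: `psi = lights_off - onset` in minutes, so positive
#' means the onset precedes lights-off (phase advanced). Sign convention is
#' package-wide: advance = positive.
#'
#' @param onsets an `onset_series` from [detect_onsets()].
#' @param schedule a [light_schedule()]; onset days must be LD.
#' @param min_days minimum number of usable days (default 3).
#' @return An object of class `phase_angle`: list with `psi_min`, `sd_min`,
#'   `n_days`, `per_day` (data.frame day, psi_min).
#' @export
phase_angle_entrainment <- function(onsets, schedule, min_days = 3) {
  ok <- onsets[!onsets$flagged, , drop = FALSE]
  if (nrow(ok) < min_days)
    stop("need at least ", min_days, " unflagged onsets")
  for (d in ok$day)
    if (!day_info(schedule, d)$is_ld)
      stop("phase angle of entrainment requires LD days (day ", d, ")")
  psi <- wrap_min((lights_off_time(schedule, ok$day) - ok$onset_h) * 60)
  structure(list(psi_min = mean(psi), sd_min = stats::sd(psi),
                 n_days = nrow(ok),
                 per_day = data.frame(day = ok$day, psi_min = psi)),
            class = "phase_angle")
}

#' @export
print.phase_angle <- function(x, ...) {
  cat(sprintf(
    "<phase_angle> psi = %+.2f +/- %.2f min over %d day(s) (positive = advanced)\n",
    x$psi_min, x$sd_min, x$n_days))
  invisible(x)
}

#' Free-running period (tau)
#'
#' `method = "onset_regression"` fits a least-squares line of absolute onset
#' time against circadian cycle index; tau is the slope (min/cycle,
#' converted to hours) and the 95% CI comes from the slope's CI. The integer
#' number of cycles between successive onsets is re-assigned from the
#' running tau estimate, so flagged days and onsets drifting across midnight
#' do not alias the fit. `method = "periodogram"` takes the peak of
#' [chi_square_periodogram()] on the supplied series.
#'
#' @param onsets an `onset_series` (onset_regression method).
#' @param method `"onset_regression"` or `"periodogram"`.
#' @param series an [activity_series()], required for the periodogram
#'   method.
#' @param min_days minimum unflagged onsets for the regression (default 5).
#' @param ... passed to [chi_square_periodogram()].
#' @return An object of class `freerun_fit`: list with `tau_h`, `ci_95`,
#'   `method`, `n_days`.
#' @export
estimate_tau <- function(onsets = NULL,
                         method = c("onset_regression", "periodogram"),
                         series = NULL, min_days = 5, ...) {
  method <- match.arg(method)
  if (method == "periodogram") {
    if (is.null(series)) stop("periodogram method needs the activity series")
    pg <- chi_square_periodogram(series, ...)
    return(structure(list(tau_h = pg$peak_period_h,
                          ci_95 = c(NA_real_, NA_real_),
                          method = method,
                          n_days = floor(length(series$counts) *
                                           series$epoch_min / 1440)),
                     class = "freerun_fit"))
  }
  ok <- onsets[!onsets$flagged, , drop = FALSE]
  if (nrow(ok) < min_days)
    stop("need at least ", min_days, " unflagged onsets under constant conditions")
  # regress absolute onset time on circadian cycle index; the integer number
  # of cycles between successive onsets is re-assigned from the current tau
  # estimate, which is robust to skipped days and midnight crossings
  u <- ok$onset_h * 60
  dt <- diff(u)
  tau_min <- 1440
  fit <- NULL
  for (iter in 1:3) {
    cyc <- cumsum(c(0, pmax(1, round(dt / tau_min))))
    fit <- stats::lm(u ~ cyc)
    tau_min <- unname(stats::coef(fit)[2])   # min/cycle
  }
  ci <- tryCatch(suppressWarnings(stats::confint(fit)[2, ]),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(tau_h = tau_min / 60,
                 ci_95 = unname(ci / 60),
                 method = method, n_days = nrow(ok)),
            class = "freerun_fit")
}

#' @export
print.freerun_fit <- function(x, ...) {
  ci <- if (all(is.finite(x$ci_95)))
    sprintf(" (95%% CI %.2f-%.2f)", x$ci_95[1], x$ci_95[2]) else ""
  cat(sprintf("<freerun_fit> tau = %.3f h%s by %s over %d day(s)\n",
              x$tau_h, ci, x$method, x$n_days))
  invisible(x)
}

#' Phase-shift magnitude
#'
#' Fits separate onset-vs-day regression lines to a pre-event window and to
#' a post-event window (after discarding `transient_days` of transients) and
#' returns the difference between the two lines evaluated at `event_day`,
#' wrapped to +/- 12 h. Positive = phase advance (onsets earlier after the
#' event).
#'
#' @param onsets an `onset_series`.
#' @param event_day day index of the shift event (light pulse or schedule
#'   advance).
#' @param pre_window_days,post_window_days window lengths, days.
#' @param transient_days post-event days discarded as transients.
#' @return Signed shift in minutes.
#' @export
phase_shift_magnitude <- function(onsets, event_day, pre_window_days = 7,
                                  post_window_days = 7, transient_days = 3) {
  ok <- onsets[!onsets$flagged, , drop = FALSE]
  pre <- ok[ok$day >= event_day - pre_window_days & ok$day < event_day, ]
  post <- ok[ok$day >= event_day + transient_days &
               ok$day < event_day + transient_days + post_window_days, ]
  if (nrow(pre) < 2L || nrow(post) < 2L)
    stop("insufficient steady-state days in the pre or post window")
  line_at <- function(df, day0) {
    u <- unwrap_onsets(df$onset_min)
    if (stats::var(df$day) == 0) return(mean(u))
    fit <- stats::lm(u ~ df$day)
    unname(stats::coef(fit)[1] + stats::coef(fit)[2] * day0)
  }
  wrap_min(line_at(pre, event_day) - line_at(post, event_day))
}

#' Days to re-entrain after a schedule shift
#'
#' Finds the first day offset `d >= 0` after the shift event from which the
#' phase angle of entrainment stays within `criterion_min` minutes of its
#' pre-shift steady-state value for `consecutive_days` running. The
#' steady-state psi is the mean over pre-shift unflagged LD days.
#'
#' @param onsets an `onset_series`.
#' @param schedule a [light_schedule()] containing the shift event.
#' @param criterion_min re-entrainment criterion, minutes.
#' @param consecutive_days days the criterion must hold in a row.
#' @param shift_index which shift event to use (default the first).
#' @return Integer days after the shift event, or `NA` with a warning when
#'   the record never re-entrains ("not re-entrained" sentinel).
#' @export
reentrainment_time <- function(onsets, schedule, criterion_min = 30,
                               consecutive_days = 3, shift_index = 1L) {
  if (is.null(schedule$shifts) || nrow(schedule$shifts) < shift_index)
    stop("schedule has no shift event at index ", shift_index)
  e <- schedule$shifts$day[shift_index]
  ok <- onsets[!onsets$flagged, , drop = FALSE]
  pre <- ok[ok$day < e, , drop = FALSE]
  pre <- pre[vapply(pre$day, function(d) day_info(schedule, d)$is_ld,
                    logical(1)), , drop = FALSE]
  if (nrow(pre) < 1L) stop("no pre-shift onsets to define steady-state psi")
  psi_ss <- mean(wrap_min((lights_off_time(schedule, pre$day) -
                             pre$onset_h) * 60))
  post <- ok[ok$day >= e, , drop = FALSE]
  if (nrow(post) < 1L) stop("no post-shift onsets available")
  psi_post <- wrap_min((lights_off_time(schedule, post$day) -
                          post$onset_h) * 60)
  within <- abs(psi_post - psi_ss) < criterion_min
  d_off <- post$day - e
  for (k in seq_along(d_off)) {
    if (!within[k]) next
    run <- which(d_off >= d_off[k] & d_off < d_off[k] + consecutive_days)
    if (all(within[run])) return(as.integer(d_off[k]))
  }
  warning("not re-entrained within the record")
  NA_integer_
}

#' Negative-masking index
#'
#' Percent suppression of activity during a light pulse relative to the mean
#' activity in the same clock-time window on baseline days:
#' `100 * (1 - A_pulse / A_baseline)`. 100 = complete suppression; negative
#' values indicate positive masking.
#'
#' @param series an [activity_series()].
#' @param schedule a [light_schedule()] containing the pulse.
#' @param pulse_index which pulse to score.
#' @param baseline_days integer day indices supplying baseline activity in
#'   the matching clock-time window.
#' @return Percent suppression (<= 100; may be negative).
#' @export
masking_index <- function(series, schedule, pulse_index = 1L,
                          baseline_days) {
  p <- schedule$pulses
  if (is.null(p) || nrow(p) < pulse_index)
    stop("schedule has no pulse at index ", pulse_index)
  start <- p$start_h[pulse_index]
  dur_h <- p$duration_min[pulse_index] / 60
  t0 <- epoch_starts(series)
  window_total <- function(w0) {
    sum(series$counts[t0 >= w0 & t0 < w0 + dur_h & !series$gap])
  }
  a_pulse <- window_total(start)
  clock <- start %% 24
  a_base <- vapply(baseline_days, function(d) window_total(24 * d + clock),
                   numeric(1))
  if (mean(a_base) == 0) stop("zero baseline activity; masking undefined")
  100 * (1 - a_pulse / mean(a_base))
}
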