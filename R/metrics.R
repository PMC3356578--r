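#' Light-phase activity share
#'
#' Percentage of total activity counts emitted during the scheduled light
#' phase, computed over complete LD days. This is the statistic behind
#' "increased light-phase activity" comparisons between genotypes.
#'
#' @param series an [activity_series()].
#' @param schedule a [light_schedule()]; the covered days must be LD.
#' @return Percent in `[0, 100]`.
#' @export
light_phase_activity_pct <- function(series, schedule) {
  cd <- complete_day_index(series)
  if (length(cd$days) < 1L) stop("need at least one complete day")
  for (d in cd$days)
    if (!day_info(schedule, d)$is_ld)
      stop("light_phase_activity_pct requires LD days (day ", d,
           " is DD/LL)")
  idx <- cd$idx[!series$gap[cd$idx]]
  tot <- sum(series$counts[idx])
  if (tot == 0) stop("total counts are zero; share undefined")
  s_nopulse <- schedule; s_nopulse$pulses <- NULL
  light <- is_light(s_nopulse, epoch_starts(series)[idx])
  100 * sum(series$counts[idx][light]) / tot
}

# rebin + fold helper shared by IS and the periodogram-style statistics
fold_for_metric <- function(series, bins_per_day) {
  if (1440 %% bins_per_day != 0)
    stop("bins_per_day must divide 1440")
  target <- 1440 / bins_per_day
  if (target < series$epoch_min)
    stop("bins_per_day finer than the recording epoch")
  rebin(series, target)
}

#' Interdaily stability (IS)
#'
#' Day-to-day reproducibility of the 24-h activity profile:
#' `IS = N * sum_h (xbar_h - xbar)^2 / (p * sum_i (x_i - xbar)^2)` where `p`
#' is bins per day, `N` the number of (complete-day) bins, `xbar_h` the
#' across-days mean of bin `h`. IS is 1 for a perfectly repeated daily
#' pattern and approaches `p/N` for white noise. Computed after rebinning to
#' `bins_per_day` (1-h bins by default, the literature convention);
#' gap-masked bins are excluded from means and from `N`.
#'
#' @param series an [activity_series()].
#' @param bins_per_day bins per 24 h after rebinning (default 24).
#' @return IS in `[0, 1]`.
#' @export
interdaily_stability <- function(series, bins_per_day = 24) {
  s <- fold_for_metric(series, bins_per_day)
  p <- bins_per_day
  m <- length(s$counts) %/% p
  if (m < 2L) stop("need at least 2 complete days")
  x <- s$counts[seq_len(m * p)]
  x[s$gap[seq_len(m * p)]] <- NA
  mat <- matrix(x, nrow = m, ncol = p, byrow = TRUE)
  xbar_h <- colMeans(mat, na.rm = TRUE)
  xbar <- mean(x, na.rm = TRUE)
  n_valid <- sum(!is.na(x))
  ss_tot <- sum((x - xbar)^2, na.rm = TRUE)
  if (ss_tot == 0) stop("zero variance; IS undefined")
  n_valid * sum((xbar_h - xbar)^2) / (p * ss_tot)
}

#' Intradaily variability (IV)
#'
#' Fragmentation of the activity rhythm via normalized successive
#' differences: `IV = N * sum_{i>=2} (x_i - x_{i-1})^2 /
#' ((N - 1) * sum_i (x_i - xbar)^2)`. IV is near 0 for smooth rhythms,
#' approximately 2 for white noise and reaches 4 for strict alternation.
#' Computed on `bins_per_day` rebinned data; differences across gap-masked
#' bins are excluded.
#'
#' @inheritParams interdaily_stability
#' @return IV >= 0.
#' @export
intradaily_variability <- function(series, bins_per_day = 24) {
  s <- fold_for_metric(series, bins_per_day)
  x <- s$counts
  x[s$gap] <- NA
  if (sum(!is.na(x)) < 2L) stop("need at least 2 bins")
  xbar <- mean(x, na.rm = TRUE)
  ss_tot <- sum((x - xbar)^2, na.rm = TRUE)
  if (ss_tot == 0) stop("zero variance; IV undefined")
  d <- diff(x)
  n_valid <- sum(!is.na(x))
  sum(d^2, na.rm = TRUE) * n_valid / ((n_valid - 1) * ss_tot)
}

#' Detect activity bouts
#'
#' A bout is a maximal run of epochs with counts at or above
#' `count_threshold`, where sub-threshold gaps no longer than `max_gap_min`
#' are absorbed into the bout; merged bouts shorter than `min_bout_min` are
#' discarded. Counts are totalled over the bout's whole span (gaps
#' included).
#'
#' @param series an [activity_series()].
#' @param count_threshold minimum counts per epoch to be "active".
#' @param min_bout_min minimum merged-bout duration, minutes.
#' @param max_gap_min maximum tolerated sub-threshold gap, minutes.
#' @return data.frame with columns `start_h`, `end_h`, `duration_min`,
#'   `total_counts` (zero rows if no bouts).
#' @export
detect_bouts <- function(series, count_threshold = 1, min_bout_min = 10,
                         max_gap_min = 30) {
  if (count_threshold < 0 || min_bout_min < 0 || max_gap_min < 0)
    stop("thresholds must be >= 0")
  active <- series$counts >= count_threshold
  ep <- series$epoch_min
  empty <- data.frame(start_h = numeric(0), end_h = numeric(0),
                      duration_min = numeric(0), total_counts = numeric(0))
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # absorb short sub-threshold gaps between consecutive active runs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) for (k in 2:nrow(runs)) {
    gap_ep <- runs$start[k] - merged$end[nrow(merged)] - 1L
    if (gap_ep * ep <= max_gap_min) {
      merged$end[nrow(merged)] <- runs$end[k]
    } else {
      merged <- rbind(merged, runs[k, ])
    }
  }
  dur <- (merged$end - merged$start + 1L) * ep
  keep <- dur >= min_bout_min
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  t0 <- epoch_starts(series)
  data.frame(
    start_h = t0[merged$start],
    end_h = t0[merged$end] + ep / 60,
    duration_min = dur[keep],
    total_counts = vapply(seq_len(nrow(merged)), function(k)
      sum(series$counts[merged$start[k]:merged$end[k]]), numeric(1)))
}

#' Mean activity bouts per day
#'
#' Applies [detect_bouts()] separately to each complete day and averages the
#' per-day bout counts.
#'
#' @inheritParams detect_bouts
#' @return Mean bouts/day.
#' @export
bouts_per_day <- function(series, count_threshold = 1, min_bout_min = 10,
                          max_gap_min = 30) {
  cd <- complete_day_index(series)
  if (length(cd$days) < 1L) stop("need at least one complete day")
  per_day <- vapply(cd$days, function(d) {
    ii <- which(cd$day_of == d)
    day_series <- activity_series(series$counts[ii], series$epoch_min,
                                  start_h = 24 * d,
                                  subject_id = series$subject_id,
                                  gap = series$gap[ii])
    nrow(detect_bouts(day_series, count_threshold, min_bout_min,
                      max_gap_min))
  }, numeric(1))
  mean(per_day)
}
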