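# Shared fixtures and independent brute-force oracles. Oracles deliberately
# re-derive each statistic with plain loops so they share no code with the
# implementations they check.

make_onsets <- function(day, onset_min, flagged = FALSE) {
  df <- data.frame(day = day, onset_min = onset_min,
                   onset_h = 24 * day + onset_min / 60,
                   flagged = rep_len(flagged, length(day)))
  class(df) <- c("onset_series", "data.frame")
  df
}

subset_onsets <- function(onsets, keep) {
  out <- onsets[keep, , drop = FALSE]
  class(out) <- c("onset_series", "data.frame")
  out
}

# interdaily stability by explicit double loop over days and bins
is_oracle <- function(mat) {
  n_days <- nrow(mat); p <- ncol(mat); n <- n_days * p
  xbar <- sum(mat) / n
  num <- 0
  for (h in seq_len(p)) {
    xh <- 0
    for (d in seq_len(n_days)) xh <- xh + mat[d, h]
    xh <- xh / n_days
    num <- num + (xh - xbar)^2
  }
  den <- 0
  for (d in seq_len(n_days)) for (h in seq_len(p))
    den <- den + (mat[d, h] - xbar)^2
  n * num / (p * den)
}

# intradaily variability by direct formula evaluation
iv_oracle <- function(x) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  n * num / ((n - 1) * sum((x - xbar)^2))
}

# exhaustive bout scan applying the threshold/merge/minimum rules literally
bouts_oracle <- function(counts, epoch_min, count_threshold, min_bout_min,
                         max_gap_min) {
  active <- counts >= count_threshold
  runs <- list()
  i <- 1
  while (i <= length(active)) {
    if (active[i]) {
      j <- i
      while (j < length(active) && active[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(data.frame(start = integer(0),
                                           end = integer(0)))
  merged <- list(runs[[1]])
  for (k in seq_along(runs)[-1]) {
    prev <- merged[[length(merged)]]
    gap <- (runs[[k]][1] - prev[2] - 1) * epoch_min
    if (gap <= max_gap_min) merged[[length(merged)]] <- c(prev[1],
                                                          runs[[k]][2])
    else merged[[length(merged) + 1]] <- runs[[k]]
  }
  keep <- vapply(merged, function(r) (r[2] - r[1] + 1) * epoch_min >=
                   min_bout_min, logical(1))
  merged <- merged[keep]
  data.frame(start = vapply(merged, `[`, numeric(1), 1),
             end = vapply(merged, `[`, numeric(1), 2))
}

# Sokolove-Bushell Qp at one period by direct fold-and-sum
qp_oracle <- function(x, k) {
  m <- length(x) %/% k
  xx <- x[seq_len(m * k)]
  xh <- numeric(k)
  for (h in seq_len(k)) for (d in seq_len(m))
    xh[h] <- xh[h] + xx[(d - 1) * k + h]
  xh <- xh / m
  xbar <- mean(xx)
  m * length(xx) * sum((xh - xbar)^2) / sum((xx - xbar)^2)
}

noiseless_config <- function(...) {
  args <- modifyList(list(psi_min = 0, onset_jitter_sd_min = 0,
                          count_model = "deterministic", gap_mean_min = 0,
                          light_leak_frac = 0), list(...))
  do.call(sim_config, args)
}
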