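#' Simulation configuration
#'
#' Ground-truth parameters of the phenomenological activity generator. The
#' generator is a banded alternating-renewal process, not a limit-cycle
#' oscillator: each day has a nightly activity band whose onset is set by the
#' entrainment phase angle under LD, drifts at the free-running period under
#' constant conditions, and relaxes geometrically to a shifted schedule;
#' counts within the band come from a bout/gap renewal process with a chosen
#' count model. Every parameter maps one-to-one to an estimator in the
#' package, so parameter recovery is a complete test of the analysis battery.
#'
#' @param tau_h free-running period, hours (in `[20, 28]`). Onsets drift at
#'   `tau_h - 24` h/day under DD/LL.
#' @param psi_min mean phase angle of entrainment, minutes; positive = onset
#'   precedes lights-off (advanced).
#' @param onset_jitter_sd_min day-to-day SD of the onset, minutes.
#' @param active_phase_h duration of the nightly activity band, hours.
#' @param counts_per_active_epoch mean count intensity per in-bout epoch.
#' @param count_model `"deterministic"` (counts = expected intensity),
#'   `"poisson"`, or `"negbin"` (with `dispersion` = size parameter).
#' @param dispersion negative-binomial size (ignored otherwise).
#' @param bout_mean_min,gap_mean_min mean bout and gap durations (minutes) of
#'   the alternating exponential renewal process inside the band;
#'   `gap_mean_min = 0` (or infinite `bout_mean_min`) gives a continuous
#'   band.
#' @param light_leak_frac fraction of each day's expected counts relocated
#'   uniformly into the scheduled light phase, in `[0, 1]`. Relocation
#'   conserves the day's expected total.
#' @param masking_coeff fractional suppression of activity during unscheduled
#'   light (pulses), in `[0, 1]`; 1 = complete negative masking.
#' @param reentrain_rate_frac_per_day fraction of the remaining phase
#'   displacement recovered per day after a schedule shift, in `(0, 1]`.
#' @param seed integer RNG seed; simulations are bit-reproducible given the
#'   seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tau_h = 23.8, psi_min = 10, onset_jitter_sd_min = 8,
                       active_phase_h = 10, counts_per_active_epoch = 30,
                       count_model = c("poisson", "negbin", "deterministic"),
                       dispersion = 5,
                       bout_mean_min = 120, gap_mean_min = 0,
                       light_leak_frac = 0, masking_coeff = 0,
                       reentrain_rate_frac_per_day = 0.5, seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(tau_h = tau_h, psi_min = psi_min,
              onset_jitter_sd_min = onset_jitter_sd_min,
              active_phase_h = active_phase_h,
              counts_per_active_epoch = counts_per_active_epoch,
              count_model = count_model, dispersion = dispersion,
              bout_mean_min = bout_mean_min, gap_mean_min = gap_mean_min,
              light_leak_frac = light_leak_frac,
              masking_coeff = masking_coeff,
              reentrain_rate_frac_per_day = reentrain_rate_frac_per_day,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg)
  stopifnot_msg(cfg$tau_h >= 20 && cfg$tau_h <= 28, "tau_h must be in [20,28]")
  for (f in c("light_leak_frac", "masking_coeff"))
    stopifnot_msg(cfg[[f]] >= 0 && cfg[[f]] <= 1,
                  paste(f, "must be in [0,1]"))
  stopifnot_msg(cfg$reentrain_rate_frac_per_day > 0 &&
                  cfg$reentrain_rate_frac_per_day <= 1,
                "reentrain_rate_frac_per_day must be in (0,1]")
  stopifnot_msg(cfg$active_phase_h > 0 && cfg$active_phase_h < 24,
                "active_phase_h must be in (0,24)")
  stopifnot_msg(cfg$onset_jitter_sd_min >= 0, "jitter SD must be >= 0")
  stopifnot_msg(cfg$counts_per_active_epoch >= 0, "intensity must be >= 0")
  stopifnot_msg(cfg$bout_mean_min > 0, "bout_mean_min must be > 0")
  stopifnot_msg(cfg$gap_mean_min >= 0, "gap_mean_min must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  tau %g h, psi %+g min, jitter SD %g min, band %g h\n",
              x$tau_h, x$psi_min, x$onset_jitter_sd_min, x$active_phase_h))
  cat(sprintf("  counts %g/epoch (%s), bouts %g/%g min, leak %.0f%%, masking %.0f%%, re-entrain %g/day, seed %d\n",
              x$counts_per_active_epoch, x$count_model, x$bout_mean_min,
              x$gap_mean_min, 100 * x$light_leak_frac,
              100 * x$masking_coeff, x$reentrain_rate_frac_per_day, x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Ground-truth onset (absolute hours) for each simulated day.
sim_onsets <- function(config, schedule, n_days) {
  onsets <- numeric(n_days)
  deficit_min <- 0           # actual - steady-state, minutes
  prev_onset <- NA_real_
  rate <- config$reentrain_rate_frac_per_day
  shifts <- schedule$shifts
  for (d in seq_len(n_days) - 1L) {
    info <- day_info(schedule, d)
    if (info$is_ld) {
      steady <- lights_off_time(schedule, d) - config$psi_min / 60
      if (!is.null(shifts) && any(shifts$day == d)) {
        # schedule jumped; behaviour keeps yesterday's phase and relaxes
        adv <- sum(shifts$advance_h[shifts$day == d])
        deficit_min <- deficit_min + adv * 60
      } else if (deficit_min != 0) {
        deficit_min <- deficit_min * (1 - rate)
        if (abs(deficit_min) < 1e-9) deficit_min <- 0
      }
      onsets[d + 1L] <- steady + deficit_min / 60
    } else {
      # free run: continue from the previous day's onset at period tau;
      # with no prior day, anchor at the nominal lights-off the segment's
      # lights_on would imply under 12:12 LD
      onsets[d + 1L] <- if (!is.na(prev_onset)) prev_onset + config$tau_h
      else 24 * d + ((info$lights_on + 12) %% 24) - config$psi_min / 60
    }
    prev_onset <- onsets[d + 1L]
  }
  onsets
}

#' Simulate a wheel-running activity series
#'
#' Generates one subject's activity-count series under a lighting schedule
#' with all circadian parameters known. Under LD the nightly onset sits at
#' `lights_off - psi_min` (plus Gaussian jitter); under DD/LL it drifts at
#' `tau_h - 24` h/day; after a schedule shift the onset approaches the new
#' steady state geometrically at `reentrain_rate_frac_per_day`. Counts inside
#' the band follow the bout/gap renewal process and the chosen count model; a
#' `light_leak_frac` share of each day's expected counts is relocated
#' uniformly over that day's scheduled-light epochs (conserving the expected
#' daily total), and activity during unscheduled light (pulses) is multiplied
#' by `1 - masking_coeff`.
#'
#' The returned series carries the per-day ground-truth onsets as
#' `attr(, "truth")`.
#'
#' @param config a [sim_config()].
#' @param schedule a [light_schedule()].
#' @param n_days number of days to simulate (>= 1).
#' @param epoch_min epoch length in minutes; must divide 1440.
#' @param subject_id,group metadata labels for the output series.
#' @return An [activity_series()] of `n_days * 1440 / epoch_min` epochs.
#' @export
simulate_activity <- function(config, schedule, n_days, epoch_min = 10,
                              subject_id = "sim1", group = NA_character_) {
  validate_sim_config(config)
  if (n_days < 1L) stop("n_days must be >= 1")
  if (1440 %% epoch_min != 0) stop("epoch_min must divide 1440")
  with_seed(config$seed, {
    n_ep <- as.integer(n_days * 1440 / epoch_min)
    t0 <- (seq_len(n_ep) - 1L) * epoch_min / 60      # epoch starts, hours
    onsets <- sim_onsets(config, schedule, n_days)
    if (config$onset_jitter_sd_min > 0)
      onsets <- onsets + stats::rnorm(n_days, 0,
                                      config$onset_jitter_sd_min) / 60
    # expected intensity from the banded bout/gap process
    lambda <- numeric(n_ep)
    continuous <- config$gap_mean_min <= 0 || !is.finite(config$bout_mean_min)
    for (d in seq_len(n_days)) {
      band <- c(onsets[d], onsets[d] + config$active_phase_h)
      if (continuous) {
        segs <- matrix(band, ncol = 2)
      } else {
        segs <- NULL
        pos <- band[1]
        in_bout <- TRUE
        while (pos < band[2]) {
          dur <- stats::rexp(1, 1 / (if (in_bout) config$bout_mean_min
                                     else config$gap_mean_min)) / 60
          if (in_bout)
            segs <- rbind(segs, c(pos, min(pos + dur, band[2])))
          pos <- pos + dur
          in_bout <- !in_bout
        }
      }
      # per-epoch covered fraction
      for (k in seq_len(nrow(segs))) {
        i0 <- max(1L, floor(segs[k, 1] * 60 / epoch_min) + 1L)
        i1 <- min(n_ep, ceiling(segs[k, 2] * 60 / epoch_min))
        if (i1 < i0) next
        ii <- i0:i1
        lo <- pmax(t0[ii], segs[k, 1])
        hi <- pmin(t0[ii] + epoch_min / 60, segs[k, 2])
        lambda[ii] <- lambda[ii] +
          config$counts_per_active_epoch * pmax(hi - lo, 0) /
          (epoch_min / 60)
      }
    }
    # light-phase leak: relocate a share of each day's expected counts
    horizon <- 24 * (last_day(schedule) + 1)
    in_range <- t0 < horizon
    sched_light <- rep(FALSE, n_ep)
    s_nopulse <- schedule; s_nopulse$pulses <- NULL
    sched_light[in_range] <- is_light(s_nopulse, t0[in_range])
    if (config$light_leak_frac > 0) {
      day_of <- floor(t0 / 24)
      for (d in unique(day_of)) {
        ii <- which(day_of == d)
        li <- ii[sched_light[ii]]
        tot <- sum(lambda[ii])
        if (length(li) == 0L || tot == 0) next
        lambda[ii] <- lambda[ii] * (1 - config$light_leak_frac)
        lambda[li] <- lambda[li] +
          config$light_leak_frac * tot / length(li)
      }
    }
    # negative masking during unscheduled light (pulses in the dark)
    if (config$masking_coeff > 0 && !is.null(schedule$pulses)) {
      pulsed <- in_pulse(schedule, t0) & !sched_light
      lambda[pulsed] <- lambda[pulsed] * (1 - config$masking_coeff)
    }
    counts <- switch(config$count_model,
                     deterministic = lambda,
                     poisson = stats::rpois(n_ep, lambda),
                     negbin = ifelse(lambda > 0,
                                     stats::rnbinom(n_ep, mu = lambda,
                                                    size = config$dispersion),
                                     0))
    out <- activity_series(counts, epoch_min, 0, subject_id, group)
    attr(out, "truth") <- data.frame(day = seq_len(n_days) - 1L,
                                     onset_h = onsets)
    attr(out, "config") <- config
    out
  })
}

#' Simulate a labelled two-group cohort
#'
#' Per-animal seeds are derived deterministically from `base_seed`, the group
#' label and the within-group index, so cohorts are reproducible while
#' animals have independent streams.
#'
#' @param config_control,config_mutant [sim_config()]s for the two groups
#'   (seeds inside them are overridden per animal).
#' @param n_per_group animals per group (>= 1).
#' @param schedule a [light_schedule()].
#' @param n_days days to simulate.
#' @param base_seed integer master seed.
#' @param epoch_min epoch length, minutes.
#' @param labels group labels, length 2 (control first).
#' @return A list of `2 * n_per_group` [activity_series()] with `group` set;
#'   `attr(, "manifest")` is a data.frame (subject_id, group, seed).
#' @export
simulate_cohort <- function(config_control, config_mutant, n_per_group,
                            schedule, n_days, base_seed = 1L,
                            epoch_min = 10,
                            labels = c("control", "mutant")) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  out <- list(); manifest <- NULL
  for (g in 1:2) {
    cfg <- if (g == 1L) config_control else config_mutant
    lab <- labels[g]
    hash <- sum(utf8ToInt(lab)) %% 1000L
    for (i in seq_len(n_per_group)) {
      seed_i <- as.integer((base_seed + 104729 * (g - 1) + 7919 * i +
                              hash * 31) %% 2147483629)
      cfg_i <- cfg; cfg_i$seed <- seed_i
      sid <- sprintf("%s_%02d", lab, i)
      out[[sid]] <- simulate_activity(cfg_i, schedule, n_days, epoch_min,
                                      subject_id = sid, group = lab)
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = lab,
                                   seed = seed_i))
    }
  }
  attr(out, "manifest") <- manifest
  out
}

#' Simulate a sparsely sampled 24-h biomarker profile
#'
#' Values follow `mesor + amplitude * cos(2*pi*(zt - acrophase_h)/24)` plus
#' Gaussian noise, with `n_reps` replicates per sampled ZT — the sampling
#' design of cross-sectional SCN neuropeptide or serum hormone time courses.
#'
#' @param acrophase_h peak time, ZT hours.
#' @param mesor rhythm-adjusted mean.
#' @param amplitude half peak-to-trough range (>= 0).
#' @param sample_zts ZT hours at which samples are taken (non-empty).
#' @param n_reps replicates per ZT (>= 1).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @param group group label.
#' @return A `profile_sample`: data.frame with columns `zt_h`, `value`,
#'   `replicate` and attribute `group`.
#' @export
simulate_profile <- function(acrophase_h, mesor, amplitude, sample_zts,
                             n_reps = 4, noise_sd = 0, seed = 1L,
                             group = "g") {
  if (length(sample_zts) == 0L) stop("sample_zts must be non-empty")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  with_seed(seed, {
    zt <- rep(sample_zts, each = n_reps)
    mu <- mesor + amplitude * cos(2 * pi * (zt - acrophase_h) / 24)
    val <- mu + if (noise_sd > 0) stats::rnorm(length(zt), 0, noise_sd) else 0
    profile_sample(data.frame(zt_h = zt, value = val,
                              replicate = rep(seq_len(n_reps),
                                              times = length(sample_zts))),
                   group = group)
  })
}

#' Construct a profile sample
#'
#' @param df data.frame with columns `zt_h` (in `[0,24)`), `value` and
#'   optionally `replicate`.
#' @param group group label.
#' @return A `profile_sample` data.frame.
#' @export
profile_sample <- function(df, group = "g") {
  df <- as.data.frame(df)
  if (!all(c("zt_h", "value") %in% names(df)))
    stop("profile needs columns zt_h, value")
  if (any(df$zt_h < 0 | df$zt_h >= 24)) stop("zt_h must lie in [0,24)")
  if (is.null(df$replicate))
    df$replicate <- stats::ave(df$value, df$zt_h, FUN = seq_along)
  structure(df, group = group, class = c("profile_sample", "data.frame"))
}
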