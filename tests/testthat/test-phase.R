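test_that("noiseless onsets are recovered on the epoch grid and zero days flagged", {
  s <- ld_schedule()
  a <- simulate_activity(noiseless_config(), s, 7)
  o <- detect_onsets(a)
  expect_false(any(o$flagged))
  expect_equal(o$onset_min, rep(1140, 7))   # lights-off 19:00
  # silence one full day
  a2 <- a
  a2$counts[(3 * 144 + 1):(4 * 144)] <- 0
  o2 <- detect_onsets(a2)
  expect_true(o2$flagged[o2$day == 3])
  expect_error(detect_onsets(activity_series(rpois(10, 2), 10)), "complete day")
})

test_that("detected onset jitter stays within twice the injected SD", {
  s <- ld_schedule()
  a <- simulate_activity(sim_config(psi_min = 0, onset_jitter_sd_min = 8,
                                    count_model = "poisson",
                                    gap_mean_min = 0, seed = 5), s, 14)
  o <- detect_onsets(a)
  sd_det <- sd(o$onset_min[!o$flagged])
  expect_lt(sd_det, 16)
  expect_gt(sd_det, 2)
})

test_that("phase angle of entrainment follows its sign convention", {
  s <- ld_schedule()
  o0 <- make_onsets(0:6, rep(1140, 7))           # exactly at lights-off
  expect_equal(phase_angle_entrainment(o0, s)$psi_min, 0)
  o20 <- make_onsets(0:6, rep(1120, 7))          # 18:40, 20 min early
  expect_equal(phase_angle_entrainment(o20, s)$psi_min, 20)
  expect_error(phase_angle_entrainment(make_onsets(0:1, c(1140, 1140)), s),
               "at least 3")
  expect_error(phase_angle_entrainment(o0, dd_schedule()), "LD")
})

test_that("psi is invariant to count rescaling", {
  s <- ld_schedule()
  a <- simulate_activity(sim_config(psi_min = 15, onset_jitter_sd_min = 6,
                                    count_model = "poisson",
                                    gap_mean_min = 0, seed = 2), s, 10)
  a5 <- a
  a5$counts <- a$counts * 5
  expect_equal(phase_angle_entrainment(detect_onsets(a), s)$psi_min,
               phase_angle_entrainment(detect_onsets(a5), s)$psi_min)
})

test_that("tau estimation: exact on noiseless drift, 24 for constant onsets", {
  expect_equal(estimate_tau(make_onsets(0:9, rep(1100, 10)))$tau_h, 24)
  for (tau in c(23, 25, 25.5)) {
    a <- simulate_activity(noiseless_config(tau_h = tau),
                           dd_schedule(n_days = 20, ld_days = 5), 25)
    od <- detect_onsets(a)
    fit <- estimate_tau(subset_onsets(od, od$day >= 6 & !od$flagged))
    expect_equal(fit$tau_h, tau, tolerance = 1e-6)
    # onset regression and periodogram peak agree within a grid step
    pg_tau <- estimate_tau(method = "periodogram", series = a)$tau_h
    expect_lt(abs(pg_tau - fit$tau_h), 1 / 6 + 1e-9)
  }
  expect_error(estimate_tau(make_onsets(0:2, rep(1100, 3))), "at least 5")
})

test_that("tau CI covers a jittered injected period in most replicates", {
  tau <- 23.6
  cover <- vapply(1:100, function(r) {
    a <- simulate_activity(sim_config(tau_h = tau, psi_min = 0,
                                      onset_jitter_sd_min = 8,
                                      count_model = "poisson",
                                      gap_mean_min = 0, seed = r),
                           dd_schedule(n_days = 14, ld_days = 3), 17)
    od <- detect_onsets(a)
    fit <- estimate_tau(subset_onsets(od, od$day >= 4 & !od$flagged))
    fit$ci_95[1] <= tau && tau <= fit$ci_95[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("phase-shift magnitude: sham is zero, injected translations recovered", {
  # sham: steady onsets, no event
  sham <- make_onsets(0:19, rep(1140, 20))
  expect_lt(abs(phase_shift_magnitude(sham, 10, 8, 6, 2)), 10)
  # +40 min advance injected as an onset translation after day 10
  shifted <- make_onsets(0:19, c(rep(1140, 10), rep(1100, 10)))
  expect_equal(phase_shift_magnitude(shifted, 10, 8, 6, 2), 40)
  expect_error(phase_shift_magnitude(make_onsets(0:3, rep(1140, 4)), 2,
                                     pre_window_days = 2,
                                     post_window_days = 2,
                                     transient_days = 2),
               "insufficient")
})

test_that("re-entrainment after a 6-h advance follows the geometric clock", {
  mk_sched <- function(adv) light_schedule(
    data.frame(start_day = 0, n_days = NA, lights_on = 7,
               photoperiod_h = 12, lux = "150 lux"),
    shifts = data.frame(day = 10, advance_h = adv))
  run <- function(rate, adv) {
    sch <- mk_sched(adv)
    a <- simulate_activity(noiseless_config(
      reentrain_rate_frac_per_day = rate), sch, 24)
    reentrainment_time(detect_onsets(a), sch, criterion_min = 30,
                       consecutive_days = 3)
  }
  # 360 * 0.5^d < 30 first at d = 4
  expect_equal(run(0.5, 6), 4L)
  expect_equal(run(1.0, 6), 1L)
  expect_equal(run(0.5, 0), 0L)
})

test_that("masking index: complete suppression is 100, no suppression is 0, recovery holds", {
  sch <- ld_schedule()
  sch$pulses <- data.frame(start_h = 24 * 5 + 21, duration_min = 60,
                           lux = "pulse")
  base_days <- c(1, 2, 3, 4, 6, 7)
  a1 <- simulate_activity(noiseless_config(masking_coeff = 1), sch, 8)
  expect_equal(masking_index(a1, sch, 1, base_days), 100)
  a0 <- simulate_activity(noiseless_config(masking_coeff = 0), sch, 8)
  expect_equal(masking_index(a0, sch, 1, base_days), 0, tolerance = 1e-8)
  mis <- vapply(1:20, function(r) {
    ar <- simulate_activity(sim_config(psi_min = 0, onset_jitter_sd_min = 0,
                                       masking_coeff = 0.7,
                                       count_model = "poisson",
                                       gap_mean_min = 0, seed = r),
                            sch, 8)
    masking_index(ar, sch, 1, base_days)
  }, numeric(1))
  expect_lt(abs(mean(mis) - 70), 10)
})
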