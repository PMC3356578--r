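test_that("light-phase share: nocturnal is 0, uniform is 50, leak is realized", {
  s <- ld_schedule()
  a0 <- simulate_activity(noiseless_config(), s, 6)
  expect_equal(light_phase_activity_pct(a0, s), 0)
  flat <- activity_series(rep(3, 6 * 144), 10)
  expect_equal(light_phase_activity_pct(flat, s), 50)
  a19 <- simulate_activity(noiseless_config(light_leak_frac = 0.19), s, 6)
  expect_equal(light_phase_activity_pct(a19, s), 19)
  expect_error(light_phase_activity_pct(a0, dd_schedule()), "LD")
  expect_error(light_phase_activity_pct(
    activity_series(rep(0, 288), 10), s), "zero")
})

test_that("IS is 1 for a periodic signal, small for noise, and matches the loop oracle", {
  pattern <- c(rep(0, 12), rep(8, 12))
  s <- activity_series(rep(pattern, 10), 60)
  expect_equal(interdaily_stability(s), 1)
  set.seed(21)
  noise <- activity_series(rpois(30 * 24, 10), 60)
  expect_lt(interdaily_stability(noise), 0.1)   # expectation ~ p/N = 1/30
  # 6 days x 4 bins printed fixture against the double-loop oracle
  fix <- c(0, 0, 10, 10,  0, 0, 10, 10,  0, 2, 8, 10,
           1, 0, 9, 10,  0, 1, 10, 9,  0, 0, 10, 10)
  sf <- activity_series(fix, 360)
  expect_equal(interdaily_stability(sf, bins_per_day = 4),
               is_oracle(matrix(fix, nrow = 6, byrow = TRUE)))
  expect_error(interdaily_stability(activity_series(rep(2, 48), 60)),
               "variance")
})

test_that("IS is invariant to count rescaling", {
  set.seed(3)
  x <- rpois(24 * 8, 6) * rep(c(rep(0.2, 12), rep(1, 12)), 8)
  s1 <- activity_series(x, 60)
  s2 <- activity_series(7.5 * x, 60)
  expect_equal(interdaily_stability(s1), interdaily_stability(s2))
})

test_that("IV hits its closed forms and is additive/scale invariant", {
  # hourly 24-h sinusoid: IV = 2 * (1 - cos(2*pi/24))
  x <- 5 + sin(2 * pi * (0:(24 * 30 - 1)) / 24)
  s <- activity_series(x, 60)
  expect_equal(intradaily_variability(s), 2 * (1 - cos(2 * pi / 24)),
               tolerance = 5e-3)   # closed form is the infinite-length limit
  # strict alternation: IV = 4
  alt <- activity_series(rep(c(0, 7), 240), 60)
  expect_equal(intradaily_variability(alt), 4, tolerance = 1e-6)
  # oracle agreement on an arbitrary series
  set.seed(13)
  y <- rpois(96, 5)
  expect_equal(intradaily_variability(activity_series(y, 60)), iv_oracle(y))
  # invariances
  expect_equal(intradaily_variability(activity_series(y + 11, 60)),
               intradaily_variability(activity_series(3 * y + 33, 60)))
})

test_that("bout detection follows the threshold/merge/minimum rules", {
  ep <- 10
  mk <- function(v) activity_series(v, ep)
  # one continuous 2-h block
  b <- detect_bouts(mk(c(rep(0, 20), rep(6, 12), rep(0, 20))),
                    count_threshold = 1, min_bout_min = 10, max_gap_min = 30)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 120)
  # two blocks: gap > max_gap splits, gap <= max_gap merges
  two <- c(rep(6, 6), rep(0, 4), rep(6, 6))       # 40-min gap
  expect_equal(nrow(detect_bouts(mk(two), 1, 10, 30)), 2)
  expect_equal(nrow(detect_bouts(mk(two), 1, 10, 40)), 1)
  # randomized series against the exhaustive oracle
  set.seed(17)
  for (r in 1:20) {
    v <- rpois(150, 0.9)
    got <- detect_bouts(mk(v), 1, 30, 20)
    want <- bouts_oracle(v, ep, 1, 30, 20)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_h * 6 + 1, want$start)
      expect_equal(got$end_h * 6, want$end)
    }
  }
})

test_that("bouts_per_day averages per complete day and matches hand enumeration", {
  day <- c(rep(0, 60), rep(5, 24), rep(0, 30), rep(5, 12), rep(0, 18))
  s3 <- activity_series(rep(day, 3), 10)
  # per day: two runs separated by a 5-h gap -> 2 bouts
  expect_equal(bouts_per_day(s3, 1, 10, 30), 2)
  one <- c(rep(0, 60), rep(5, 36), rep(0, 48))
  expect_equal(bouts_per_day(activity_series(rep(one, 7), 10), 1, 10, 30), 1)
})
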