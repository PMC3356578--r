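test_that("lighting state follows segments and pulses", {
  s <- ld_schedule()
  expect_true(is_light(s, 24 * 3 + 12))      # noon, day 3
  expect_false(is_light(s, 24 * 3 + 20))     # 20:00, dark
  expect_false(is_light(dd_schedule(), 50))
  expect_true(is_light(ll_schedule(), 50))
  # 30-min pulse lights up a DD night
  sp <- dd_schedule(n_days = 10)
  sp$pulses <- data.frame(start_h = 24 * 2 + 21, duration_min = 30,
                          lux = "pulse")
  expect_true(is_light(sp, 24 * 2 + 21.25))
  expect_false(is_light(sp, 24 * 2 + 21.75))
  expect_error(is_light(ld_schedule(n_days = 5), 24 * 7), "timeline")
})

test_that("exactly half of a 12:12 day is light and ZT0 is lights-on", {
  s <- ld_schedule()
  for (ep in c(10, 30, 60)) {
    starts <- 24 * 2 + (seq_len(1440 / ep) - 1) * ep / 60
    expect_equal(sum(is_light(s, starts)), length(starts) / 2)
  }
  for (d in 0:6) {
    expect_equal(as.numeric(zt_of(s, lights_on_time(s, d))), 0)
    expect_equal(as.numeric(zt_of(s, lights_on_time(s, d) + 6)), 6)
  }
  expect_equal(as.numeric(zt_of(s, 19)), 12)   # lights-off boundary
})

test_that("projected ZT under constant conditions is flagged, or errors with no reference", {
  s <- dd_schedule(n_days = 10, ld_days = 3)
  z <- zt_of(s, 24 * 5 + 13)    # DD day, projecting 07:00 lights-on
  expect_equal(as.numeric(z), 6)
  expect_true(isTRUE(attr(z, "projected")))
  expect_error(zt_of(dd_schedule(n_days = 5), 30), "undefined")
})

test_that("lights_off_time handles photoperiods and errors on DD", {
  expect_equal(lights_off_time(ld_schedule(), 5), 24 * 5 + 19)
  s18 <- ld_schedule(lights_on = 6, photoperiod_h = 18)
  expect_equal(lights_off_time(s18, 0), 24)
  expect_error(lights_off_time(dd_schedule(), 2), "undefined")
})

test_that("a +6 h shift event advances lights-off by 6 h for all later days", {
  s <- light_schedule(
    data.frame(start_day = 0, n_days = NA, lights_on = 7,
               photoperiod_h = 12, lux = "150 lux"),
    shifts = data.frame(day = 10, advance_h = 6))
  for (d in 0:9) expect_equal(lights_off_time(s, d), 24 * d + 19)
  for (d in 10:15) expect_equal(lights_off_time(s, d), 24 * d + 13)
  # ZT recomputed from the shifted definition: lights on 01:00, 07:00 is ZT6
  expect_equal(as.numeric(zt_of(s, 24 * 12 + 7)), 6)
})

test_that("segment validation rejects malformed protocols", {
  expect_error(light_schedule(data.frame(start_day = 1, n_days = 5,
                                         lights_on = 7, photoperiod_h = 12,
                                         lux = "x")), "day 0")
  expect_error(light_schedule(data.frame(start_day = c(0, 7), n_days = c(5, NA),
                                         lights_on = 7, photoperiod_h = 12,
                                         lux = "x")), "contiguous")
  expect_error(light_schedule(data.frame(start_day = 0, n_days = NA,
                                         lights_on = 7, photoperiod_h = 25,
                                         lux = "x")), "photoperiod")
})

test_that("schedule config files round-trip exactly through JSON and YAML", {
  s <- light_schedule(
    data.frame(start_day = c(0L, 14L), n_days = c(14L, NA),
               lights_on = c(7, 7), photoperiod_h = c(12, 0),
               lux = c("150 lux", "DD")),
    pulses = data.frame(start_h = 24 * 16 + 21.5, duration_min = 30,
                        lux = "pulse"),
    shifts = data.frame(day = 7L, advance_h = 6))
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_schedule(s, f)
    s2 <- read_schedule(f)
    expect_equal(s2$segments$lights_on, s$segments$lights_on)
    expect_equal(s2$segments$n_days, s$segments$n_days)
    expect_equal(s2$pulses$start_h, s$pulses$start_h)
    expect_equal(s2$shifts$advance_h, s$shifts$advance_h)
    # behavioural equivalence on a grid of instants
    tt <- seq(0, 24 * 17, by = 0.25)
    expect_identical(is_light(s, tt), is_light(s2, tt))
    unlink(f)
  }
})
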