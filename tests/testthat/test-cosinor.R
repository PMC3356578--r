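test_that("cosinor reproduces a noiseless cosine exactly", {
  zt <- 0:23
  p <- profile_sample(data.frame(zt_h = zt,
                                 value = 2 + cos(2 * pi * (zt - 10) / 24)))
  fit <- cosinor_fit(p)
  expect_equal(fit$mesor, 2)
  expect_equal(fit$amplitude, 1)
  expect_equal(fit$acrophase_h, 10)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(unname(coef(fit)), c(2, 1, 10))
  expect_equal(length(residuals(fit)), 24)
})

test_that("degenerate profiles: constant flat, too-few times error", {
  flat <- profile_sample(data.frame(zt_h = c(2, 8, 14, 20),
                                    value = rep(5, 4)))
  fit <- cosinor_fit(flat)
  expect_equal(fit$amplitude, 0)
  expect_true(fit$acrophase_undefined)
  expect_true(is.na(fit$acrophase_h))
  expect_error(cosinor_fit(profile_sample(
    data.frame(zt_h = c(3, 15), value = c(1, 2)))), "3 distinct")
})

test_that("cosinor least squares agrees with an independent numeric minimizer", {
  p <- simulate_profile(7.3, 4, 1.6, seq(1, 23, by = 2), n_reps = 3,
                        noise_sd = 0.5, seed = 31)
  fit <- cosinor_fit(p)
  sse <- function(par)
    sum((p$value - par[1] - par[2] *
           cos(2 * pi * (p$zt_h - par[3]) / 24))^2)
  # coarse grid start, then Nelder-Mead refinement
  grid <- expand.grid(M = seq(3, 5, by = 0.25),
                      A = seq(0.5, 3, by = 0.25),
                      phi = seq(0, 23.5, by = 0.5))
  g0 <- grid[which.min(apply(grid, 1, sse)), ]
  opt <- optim(as.numeric(g0), sse, control = list(reltol = 1e-14,
                                                   maxit = 5000))
  expect_equal(fit$mesor, opt$par[1], tolerance = 1e-3)
  expect_equal(fit$amplitude, abs(opt$par[2]), tolerance = 1e-3)
  expect_equal(fit$acrophase_h, opt$par[3] %% 24, tolerance = 1e-3)
})

test_that("acrophase is time-translation equivariant and amplitude shift-invariant", {
  p <- simulate_profile(6, 2, 1, seq(2, 22, by = 4), n_reps = 4,
                        noise_sd = 0.2, seed = 12)
  f0 <- cosinor_fit(p)
  for (delta in c(3, 11.5, 20)) {
    p2 <- profile_sample(data.frame(zt_h = (p$zt_h + delta) %% 24,
                                    value = p$value))
    f2 <- cosinor_fit(p2)
    expect_equal(f2$acrophase_h %% 24, (f0$acrophase_h + delta) %% 24,
                 tolerance = 1e-6)
    expect_equal(f2$amplitude, f0$amplitude, tolerance = 1e-6)
  }
  p3 <- profile_sample(data.frame(zt_h = p$zt_h, value = p$value + 100))
  expect_equal(cosinor_fit(p3)$amplitude, f0$amplitude, tolerance = 1e-9)
  p4 <- profile_sample(data.frame(zt_h = p$zt_h, value = 3 * p$value))
  expect_equal(cosinor_fit(p4)$amplitude, 3 * f0$amplitude, tolerance = 1e-9)
})

test_that("acrophase recovery over 200 seeded replicates stays under 0.75 h", {
  err <- vapply(1:200, function(r) {
    pr <- simulate_profile(6, 2, 1, seq(2, 22, by = 4), n_reps = 4,
                           noise_sd = 0.25, seed = r)
    a <- cosinor_fit(pr)$acrophase_h
    abs(((a - 6 + 12) %% 24) - 12)
  }, numeric(1))
  expect_lt(mean(err), 0.75)
})

test_that("peak_bin takes the argmax ZT and flags ties", {
  p <- profile_sample(data.frame(zt_h = rep(c(2, 6, 10), each = 2),
                                 value = c(1, 1, 5, 5, 3, 3)))
  expect_equal(as.numeric(peak_bin(p)), 6)
  tie <- profile_sample(data.frame(zt_h = c(2, 6, 10), value = c(1, 5, 5)))
  expect_equal(as.numeric(peak_bin(tie)), 6)
  expect_true(attr(peak_bin(tie), "tie"))
  expect_false(attr(peak_bin(p), "tie"))
  pn <- simulate_profile(10, 2, 1, seq(2, 22, by = 4), n_reps = 1,
                         noise_sd = 0)
  expect_equal(as.numeric(peak_bin(pn)), 10)
})

test_that("group phase differences wrap circularly with advance negative", {
  mk <- function(phi) {
    zt <- seq(0, 23, by = 1)
    cosinor_fit(profile_sample(
      data.frame(zt_h = zt, value = 2 + cos(2 * pi * (zt - phi) / 24))))
  }
  expect_equal(group_phase_difference(mk(6), mk(10)), -4)
  expect_equal(group_phase_difference(mk(8), mk(8)), 0)
  expect_equal(group_phase_difference(mk(23), mk(1)), -2)
  expect_equal(group_phase_difference(mk(1), mk(23)), 2)
  expect_equal(group_phase_difference(mk(20), mk(8)), 12)
  flat <- cosinor_fit(profile_sample(
    data.frame(zt_h = c(2, 8, 14, 20), value = rep(1, 4))))
  expect_error(group_phase_difference(flat, mk(8)), "rhythm-positive")
})

test_that("group comparison matches the closed-form pooled t", {
  a <- c(5.1, 4.8, 5.5, 5.0)
  b <- c(4.2, 4.0, 4.6)
  res <- compare_groups(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_hand), length(a) + length(b) - 2)
  expect_equal(res$estimate, mean(a) - mean(b))
  expect_equal(res$p, p_hand)
  # identical groups: null effect
  res0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$estimate, 0)
  expect_gt(res0$p, 0.99)
  # large separation: decisive
  expect_lt(compare_groups(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))$p, 1e-3)
  expect_error(compare_groups(rep(1, 3), rep(1, 3)), "egenerate")
  res_a <- compare_groups(a, b, design = "anova_planned")
  expect_equal(res_a$p, res$p)
  expect_match(res_a$method, "ANOVA")
})
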