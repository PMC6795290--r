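test_that("a constant series has mesor only and undefined phases", {
  prof <- analytic_profile(M = 37, A24 = 0, A12 = 0)
  fit <- fit_cosinor(prof)
  expect_equal(fit$M, 37)
  expect_equal(c(fit$a1, fit$b1, fit$a2, fit$b2), rep(0, 4), tolerance = 1e-9)
  expect_true(is.na(fit$bathyphase))
  expect_identical(attr(fit$bathyphase, "reason"), "zero amplitude")
})

test_that("a noiseless single cosine is recovered in closed form", {
  prof <- analytic_profile(M = 36.8, A24 = 0.3, acro24 = 17, A12 = 0)
  fit <- fit_cosinor(prof)
  expect_equal(fit$M, 36.8, tolerance = 1e-9)
  expect_equal(unclass(fit$acrophase) %% 24, 17, tolerance = 1 / 60)
  expect_equal(unclass(fit$bathyphase) %% 24, 5, tolerance = 1 / 60)
})

test_that("two-harmonic mixtures match the brute-force grid oracle", {
  set.seed(10)
  for (rep in 1:20) {
    M <- runif(1, 36, 38); A24 <- runif(1, 0.1, 0.5)
    A12 <- runif(1, 0.02, 0.2)
    p24 <- runif(1, 0, 24); p12 <- runif(1, 0, 12)
    prof <- analytic_profile(M, A24, p24, A12, p12)
    fit <- fit_cosinor(prof)
    truth <- c(M, A12 * cos(2 * pi * p12 / 12), A12 * sin(2 * pi * p12 / 12),
               A24 * cos(2 * pi * p24 / 24), A24 * sin(2 * pi * p24 / 24))
    expect_equal(unname(fit$coef), truth, tolerance = 1e-6)
    orc <- oracle_extrema(M, A24, p24, A12, p12)
    expect_lt(circular_distance(fit$bathyphase, orc$bathy), 2 / 60 + 1e-9)
    expect_lt(circular_distance(fit$acrophase, orc$acro), 2 / 60 + 1e-9)
  }
})

test_that("negating the curve swaps acrophase and bathyphase", {
  prof <- analytic_profile(M = 0, A24 = 0.4, acro24 = 15, A12 = 0.1, acro12 = 3)
  neg <- prof; neg$value <- -neg$value
  f1 <- fit_cosinor(prof); f2 <- fit_cosinor(neg)
  expect_equal(unclass(f1$acrophase), unclass(f2$bathyphase))
  expect_equal(unclass(f1$bathyphase), unclass(f2$acrophase))
})

test_that("time shifts move both phases; constants move only the mesor", {
  base <- analytic_profile(M = 37, A24 = 0.3, acro24 = 10, A12 = 0.1, acro12 = 2)
  f0 <- fit_cosinor(base)
  shift_min <- 95
  shifted <- base
  shifted$value <- base$value[((base$minute - shift_min) %% 1440) / 5 + 1]
  f1 <- fit_cosinor(shifted)
  expect_lt(circular_distance(unclass(f1$acrophase),
                              unclass(f0$acrophase) + shift_min / 60), 2 / 60)
  expect_lt(circular_distance(unclass(f1$bathyphase),
                              unclass(f0$bathyphase) + shift_min / 60), 2 / 60)
  up <- base; up$value <- up$value + 2
  f2 <- fit_cosinor(up)
  expect_equal(f2$M, f0$M + 2, tolerance = 1e-9)
  expect_equal(unclass(f2$bathyphase), unclass(f0$bathyphase))
})

test_that("the fitted curve's 24-h mean equals the mesor", {
  set.seed(11)
  prof <- analytic_profile(M = 36.9, A24 = 0.35, acro24 = 18, A12 = 0.12,
                           acro12 = 4, noise_sd = 0.05)
  fit <- fit_cosinor(prof)
  grid_mean <- mean(circaphase:::cosinor_grid(unname(fit$coef)))
  expect_equal(grid_mean, fit$M, tolerance = 1e-9)
})

test_that("rank-deficient designs are refused", {
  tm <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC") + (0:9) * 86400
  x <- phys_ts(tm, rnorm(10, 37, 0.1), "S001", "core_temp")
  expect_error(fit_cosinor(x), "at least 8 distinct|rank-deficient")
})

test_that("residual bootstrap is deterministic and degenerate when noiseless", {
  prof <- analytic_profile(M = 37, A24 = 0.3, acro24 = 17, A12 = 0.08,
                           acro12 = 11)   # 12-h trough aligned at 05:00
  fit <- fit_cosinor(prof)
  ci <- bootstrap_phase_ci(fit, n_boot = 100, seed = 7)
  expect_equal(ci$bathyphase_width, 0)
  expect_equal(ci$acrophase_width, 0)
  set.seed(99)
  noisy <- analytic_profile(M = 37, A24 = 0.3, acro24 = 17, A12 = 0.08,
                            acro12 = 11, noise_sd = 0.1)
  f2 <- fit_cosinor(noisy)
  c1 <- bootstrap_phase_ci(f2, n_boot = 200, seed = 5)
  c2 <- bootstrap_phase_ci(f2, n_boot = 200, seed = 5)
  expect_identical(c1$bathyphase_ci, c2$bathyphase_ci)
  # CI contains the point estimate
  expect_lte(c1$bathyphase_ci[1], unclass(f2$bathyphase))
  expect_gte(c1$bathyphase_ci[2], unclass(f2$bathyphase))
  expect_warning(bootstrap_phase_ci(f2, n_boot = 20, seed = 1), "unstable")
})

test_that("sharp-minimum curves give narrower bathyphase than acrophase CIs", {
  # both harmonics share their minimum: sharp trough, flat double peak
  set.seed(21)
  widths <- replicate(5, {
    prof <- analytic_profile(M = 37, A24 = 0.3, acro24 = 15.5, A12 = 0.12,
                             acro12 = 3.5 + 6, noise_sd = 0.08)
    fit <- fit_cosinor(prof)
    ci <- bootstrap_phase_ci(fit, n_boot = 200, seed = 3)
    c(ci$bathyphase_width, ci$acrophase_width)
  })
  expect_lt(mean(widths[1, ]), mean(widths[2, ]))
})

test_that("dominant-period classification separates 24-h, 12-h and none", {
  s24 <- harmonic_series(4, A24 = 0.5, acro24 = 16, noise_sd = 0.15,
                         step_min = 5)
  expect_equal(classify_dominant_period(s24, seed = 1)$dominant, "24h")
  s12 <- harmonic_series(4, A24 = 0, A12 = 0.5, acro12 = 4, noise_sd = 0.15,
                         step_min = 5)
  expect_equal(classify_dominant_period(s12, seed = 1)$dominant, "12h")
  set.seed(31)
  calls <- replicate(40, {
    w <- ts_minutes(rnorm(4 * 288, 35, 0.3), channel = "chest_temp",
                    step_min = 5)
    classify_dominant_period(w, seed = sample.int(1e6, 1))$dominant
  })
  expect_gte(mean(calls == "none"), 0.9)
  expect_error(classify_dominant_period(harmonic_series(2, step_min = 5), 1),
               "3 days")
})
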