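test_that("stitching keeps pill 1 until elimination, pill 2 after", {
  p1 <- ts_minutes(rep(37, 120))
  empty <- phys_ts(as.POSIXct(character(), tz = "UTC"), numeric(),
                   "S001", "core_temp")
  expect_identical(stitch_pills(p1, empty), p1)

  # counting oracle: pill1 spans [0, 48 h); pill2 spans [24, 72 h)
  t0 <- as.POSIXct("2024-03-04", tz = "UTC")
  p1 <- phys_ts(t0 + seq(0, 48 * 3600 - 60, by = 60), rep(37, 48 * 60),
                "S001", "core_temp")
  p2 <- phys_ts(t0 + seq(24 * 3600, 72 * 3600 - 60, by = 60), rep(36.9, 48 * 60),
                "S001", "core_temp")
  st <- stitch_pills(p1, p2)
  n_after <- sum(p2$time > p1$time[nrow(p1)])
  expect_equal(nrow(st), nrow(p1) + n_after)
  expect_true(all(diff(as.numeric(st$time)) > 0))

  expect_error(stitch_pills(p1, p1), "identical start")
  far <- phys_ts(t0 + seq(100 * 3600, 130 * 3600, by = 60),
                 rep(36.8, 30 * 60 + 1), "S001", "core_temp")
  expect_warning(stitch_pills(p1, far), "gap")
})

test_that("stitching a noiseless overlap leaves no junction discontinuity", {
  cfg <- sim_config(core_noise_sd = 0, artifact_rate = 0,
                    pill_duration_range = c(1.5, 13.4))
  tr <- generate_cohort(1, seed = 5, cfg)
  p <- generate_core_temperature(tr[1, ], days = 4, seed = 5, cfg)
  st <- stitch_pills(p$pill1, p$pill2)
  jump <- abs(diff(st$value))
  expect_lt(max(jump), 0.05)   # analytic curve slope over one minute
})

test_that("artifact removal follows the window and range rules", {
  x <- ts_minutes(rep(37, 40 * 60))
  expect_identical(remove_ingestion_artifacts(x)$value, x$value)

  y <- x; y$value[10] <- 20
  cleaned <- remove_ingestion_artifacts(y)
  expect_equal(attr(cleaned, "n_removed"), 1L)
  expect_equal(nrow(cleaned), nrow(y) - 1)
  expect_false(any(cleaned$value == 20))

  z <- x; z$value[30 * 60] <- 41   # hour 30: past the artifact window
  kept <- remove_ingestion_artifacts(z)
  expect_equal(attr(kept, "n_removed"), 0L)
  expect_true(any(kept$value == 41))
})

test_that("5-minute aggregation takes left-closed clock-aligned means", {
  x <- ts_minutes(rep(37, 60))
  agg <- aggregate_5min(x)
  expect_true(all(agg$value == 37))
  expect_true(all(as.numeric(agg$time) %% 300 == 0))

  y <- ts_minutes(c(36.8, 37.0, 37.2))
  expect_equal(aggregate_5min(y)$value, 37.0)

  # counting oracle on a gappy series
  set.seed(1)
  keep <- sort(sample(1440, 800))
  tm <- as.POSIXct("2024-03-04", tz = "UTC") + (keep - 1) * 60
  g <- phys_ts(tm, rnorm(800, 37, 0.1), "S001", "core_temp")
  agg <- aggregate_5min(g)
  expect_equal(nrow(agg), length(unique((keep - 1) %/% 5)))
})

test_that("the centred 1-h moving average attenuates and preserves", {
  x5 <- ts_minutes(rep(37, 48), step_min = 5)
  expect_equal(moving_average(x5)$value, rep(37, 48))

  spike <- ts_minutes(c(rep(36.5, 24), 36.5 + 1.2, rep(36.5, 23)),
                      step_min = 5)
  sm <- moving_average(spike)
  expect_equal(sm$value[25] - 36.5, 1.2 / 12, tolerance = 1e-12)

  lin <- ts_minutes(seq(36, 38, length.out = 48), step_min = 5)
  sml <- moving_average(lin)
  interior <- 10:39
  expect_equal(diff(sml$value[interior]), diff(lin$value[interior]),
               tolerance = 1e-9)

  # adding a constant commutes with aggregate + smooth
  set.seed(2)
  z <- ts_minutes(rnorm(1440 * 2, 37, 0.2))
  chain <- function(s) moving_average(aggregate_5min(s))$value
  shifted <- ts_like(z, z$time, z$value + 1.5)
  expect_equal(chain(shifted), chain(z) + 1.5, tolerance = 1e-9)
})

test_that("averaged 24-h profiles pool bins across days", {
  two_identical <- harmonic_series(2, A24 = 0.3, acro24 = 17)
  prof <- average_24h_profile(moving_average(aggregate_5min(two_identical)))
  expect_equal(nrow(prof), 288)
  expect_true(all(prof$n[!is.na(prof$value)] >= 1))

  # bins holding v and v + delta average to v + delta/2
  t0 <- as.POSIXct("2024-03-04", tz = "UTC")
  tm <- c(t0 + seq(0, 86340, by = 300), t0 + 86400 + seq(0, 86340, by = 300))
  x <- phys_ts(tm, c(rep(37, 288), rep(37.4, 288)), "S001", "core_temp")
  prof2 <- average_24h_profile(x)
  expect_true(all(abs(prof2$value - 37.2) < 1e-12))

  # a pure 24-h cosine keeps its acrophase through the chain (grid oracle)
  pure <- harmonic_series(3, A24 = 0.3, acro24 = 17.65)
  prof3 <- preprocess_profile(pure)
  fit <- fit_cosinor(prof3)
  expect_lt(circular_distance(fit$acrophase, 17.65), 5 / 60)

  expect_error(average_24h_profile(ts_minutes(rep(37, 600))), "24 h")
})

test_that("lag correlation finds constructed shifts with the stated sign", {
  a <- harmonic_series(2, A24 = 0.5, noise_sd = 0.05)
  expect_equal(lag_correlation(a, a, 15)$best_lag, 0)
  expect_equal(lag_correlation(a, a, 15)$best_r, 1, tolerance = 1e-9)

  b <- ts_like(a, a$time + 7 * 60, a$value)   # b is a delayed by 7 min
  lc <- lag_correlation(a, b, 15)
  expect_equal(lc$best_lag, -7)

  set.seed(3)
  w1 <- ts_minutes(rnorm(2000), channel = "chest_temp")
  w2 <- ts_minutes(rnorm(2000), channel = "chest_temp")
  expect_lt(abs(lag_correlation(w1, w2, 10)$best_r), 0.15)
  short <- ts_minutes(rnorm(100))
  expect_error(lag_correlation(short, short, 10), "24 h")
})
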