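# shared fixtures, built in code at test time

ts_minutes <- function(values, start = "2024-03-04 00:00:00",
                       subject = "S001", channel = "core_temp",
                       step_min = 1) {
  tm <- as.POSIXct(start, tz = "UTC") + seq_along(values) * step_min * 60 -
    step_min * 60
  phys_ts(tm, values, subject, channel)
}

# minute series sampled from an analytic two-harmonic temperature curve
harmonic_series <- function(days, M = 37, A24 = 0.3, acro24 = 17,
                            A12 = 0, acro12 = 5, noise_sd = 0,
                            channel = "core_temp", step_min = 1) {
  n <- round(days * 1440 / step_min)
  t_h <- seq(0, by = step_min / 60, length.out = n)
  y <- M + A24 * cos(2 * pi * (t_h - acro24) / 24) +
    A12 * cos(2 * pi * (t_h - acro12) / 12)
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  ts_minutes(y, channel = channel, step_min = step_min)
}

# independent grid-search oracle for the extrema of an analytic curve
oracle_extrema <- function(M, A24, acro24, A12, acro12) {
  tg <- seq(0, 24 - 1 / 60, by = 1 / 60)
  y <- M + A24 * cos(2 * pi * (tg - acro24) / 24) +
    A12 * cos(2 * pi * (tg - acro12) / 12)
  list(acro = tg[which.max(y)], bathy = tg[which.min(y)])
}

# a daily_profile directly from an analytic curve on the 5-min grid
analytic_profile <- function(M = 37, A24 = 0.3, acro24 = 17,
                             A12 = 0.1, acro12 = 5, noise_sd = 0) {
  minute <- seq(0, 1435, by = 5)
  t_h <- minute / 60
  y <- M + A24 * cos(2 * pi * (t_h - acro24) / 24) +
    A12 * cos(2 * pi * (t_h - acro12) / 12)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  structure(data.frame(minute = minute, value = y, n = 1L),
            channel = "core_temp", subject_id = "S001",
            class = c("daily_profile", "data.frame"))
}

# truth-level phase table for regression tests (no series measurement)
truth_phase_table <- function(truth) {
  data.frame(
    subject_id = truth$subject_id,
    core_bathyphase = truth$true_core_bathyphase,
    dlmo = ifelse(truth$dlmo_missing, NA_real_, truth$true_dlmo),
    center_of_rest = truth$true_center_of_rest,
    chest_acrophase = truth$true_chest_acrophase,
    chest_bathyphase = truth$true_chest_bathyphase,
    stringsAsFactors = FALSE
  )
}

truth_subjects <- function(truth) {
  subject_record(truth$subject_id, truth$sex, truth$age, truth$bmi,
                 truth$chronotype_score)
}

# exact brute-force smoother: enumerate all 3^T state paths
enumerate_posteriors <- function(logdens, init, trans, minute) {
  T_ <- nrow(logdens); K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(1:K), T_)))
  logp <- log(init[paths[, 1]]) + logdens[cbind(1, paths[, 1])]
  for (t in 2:T_) {
    m <- minute[t - 1] + 1
    logp <- logp + log(trans[cbind(paths[, t - 1], paths[, t], m)]) +
      logdens[cbind(t, paths[, t])]
  }
  w <- exp(logp - max(logp))
  gamma <- matrix(0, T_, K)
  for (t in 1:T_) for (k in 1:K) gamma[t, k] <- sum(w[paths[, t] == k])
  list(gamma = gamma / rowSums(gamma),
       loglik = log(sum(w)) + max(logp))
}

random_toy_model <- function(seed) {
  set.seed(seed)
  theta <- lapply(1:3, function(i) matrix(rnorm(6, -1.5, 0.6), 2, 3))
  trans <- circaphase:::transition_array(theta, 3, 1)
  init <- c(0.5, 0.3, 0.2)
  mu <- c(0, 2, 4); sd <- rep(0.8, 3)
  list(trans = trans, init = init, mu = mu, sd = sd)
}

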