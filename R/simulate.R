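#' Generation parameters for synthetic cohorts
#'
#' Defaults emulate the statistical structure of the study recordings this
#' pipeline targets: ~7-day minute-level chest recordings with short
#' device-removal gaps, two ingestible-pill core temperature segments
#' swallowed 24 h apart with gastrointestinal-transit-limited durations
#' (0.2--13.4 days) and ingestion artifacts in the first hours, a 24-h +
#' 12-h harmonic temperature structure, three-regime circadian activity
#' whose rest state concentrates in a nocturnal rest span, and evening
#' salivary melatonin with a flat baseline followed by a logistic rise,
#' occasionally invalidated by >50 lux light exposure.
#'
#' Cohort-level phase dispersions are calibrated to the printed spreads of
#' the study population (bathyphase cluster near 03:30, center-of-rest near
#' 03:05, nightly chest acrophase near 03:00 with a ~9-h spread, DLMO near
#' 20:50) and the chronotype score is generated anticorrelated with the
#' phases (target rank correlation about -0.7 with center-of-rest).
#'
#' @param ... overrides for any default listed below.
#' @return a named list of generation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # latent circadian-lateness factor z ~ N(0,1) drives all phase truths
    score_center = 53, score_z_slope = -11, score_sd = 5,
    cor_center = 27.08, cor_z_slope = 1.1, cor_sd = 0.9,      # center-of-rest ~03:05
    chest_acro_center = 27.0, chest_acro_z_slope = 1.4, chest_acro_sd = 1.8,
    dlmo_center = 20.83, dlmo_z_slope = 0.8, dlmo_sd = 0.6,   # DLMO ~20:50
    # core bathyphase from the published slopes plus a calibration intercept
    eq_intercept = 19.14,
    eq_coef = c(sex = 1.33, chronotype_score = -0.058,
                center_of_rest = 0.472, chest_bathyphase = -0.145),
    eq_noise_sd = 0.8,                                        # hours
    age_range = c(21, 78), bmi_mean = 24.5, bmi_sd = 3,
    # core temperature signal
    core_mesor_mean = 37.0, core_mesor_sd = 0.15,
    core_amp24_range = c(0.2, 0.4), core_amp12_range = c(0.05, 0.15),
    core_noise_sd = 0.1,                                      # degC
    pill_duration_meanlog = log(1.6), pill_duration_sdlog = 0.55,
    pill_duration_range = c(0.2, 13.4),                       # days
    artifact_window_h = 2, artifact_rate = 0.15,
    # chest surface temperature
    chest_mesor_range = c(33.0, 36.0),
    chest_amp_dominant = c(0.8, 1.2), chest_amp_minor = c(0.1, 0.3),
    chest_amp_arrhythmic = 0.015,
    chest_noise_sd = 0.3,
    dominant_probs = c(`24h` = 0.636, `12h` = 0.273, none = 0.091),
    # activity regimes
    rest_duration_mean = 8, rest_duration_sd = 0.7,           # hours
    activity_means = c(2, 35, 180), activity_size = c(1.5, 4, 6),
    activity_regime_noise = 0.05, rest_edge_softness = 0.5,   # hours
    gap_fraction = 0.02,
    # melatonin
    mel_baseline_range = c(0.5, 2.0), mel_amplitude_range = c(8, 20),
    mel_rise_scale = 0.5, mel_noise_sd = 0.05,                # pg/mL
    lux_dim_max = 10, lux_burst_range = c(60, 300),
    lux_contam_fraction = 0.05, dlmo_missing_rate = 0.2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rng <- function(x) length(x) == 2 && x[1] <= x[2]
  if (!rng(cfg$pill_duration_range) || cfg$pill_duration_range[1] <= 0)
    stop("invalid pill_duration_range")
  if (!rng(cfg$core_amp24_range) || !rng(cfg$core_amp12_range))
    stop("invalid core amplitude range")
  if (cfg$eq_noise_sd < 0 || cfg$core_noise_sd < 0 || cfg$chest_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (abs(sum(cfg$dominant_probs) - 1) > 1e-8)
    stop("dominant_probs must sum to 1")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 0.5)
    stop("gap_fraction must be in [0, 0.5)")
  invisible(cfg)
}

## run code under a local RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## deterministic per-subject substream: depends only on (seed, index, tag)
subject_seed <- function(seed, index, tag = 0L) {
  as.integer((as.numeric(seed) * 48271 + index * 104729 + tag * 7919) %%
               2147483563)
}

sim_origin <- function() as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

#' Generate a synthetic cohort with known circadian ground truth
#'
#' Each subject's phase truths are driven by a shared latent lateness factor
#' so that chronotype score, center-of-rest, chest acrophase and DLMO are
#' mutually correlated the way field cohorts are; the true core-temperature
#' bathyphase is then computed from the published INTime slopes (sex +1.33,
#' chronotype -0.058, center-of-rest +0.472, chest bathyphase -0.145 h)
#' plus a calibration intercept and Gaussian noise. Sexes are balanced to
#' within one subject. Regeneration with the same `(n, seed, config)` is
#' bit-reproducible, and subject `i`'s record depends only on `(seed, i)`.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @param config a [sim_config()] list.
#' @return a data.frame (class `subject_truth`) with one row per subject:
#'   covariates, all true phases (unwrapped decimal hours), signal
#'   amplitudes, noise SDs, rest-span and dominant-period class.
#' @export
generate_cohort <- function(n, seed = 1L, config = sim_config()) {
  stopifnot(n >= 1)
  validate_sim_config(config)
  rows <- lapply(seq_len(n), function(i) generate_subject_truth(i, seed, config))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subject_truth", "data.frame")
  out
}

generate_subject_truth <- function(i, seed, cfg) {
  with_seed(subject_seed(seed, i, 1L), {
    sex <- as.integer(i %% 2L)                  # alternating: balanced within 1
    z <- stats::rnorm(1)
    score <- round(cfg$score_center + cfg$score_z_slope * z +
                     stats::rnorm(1, 0, cfg$score_sd))
    score <- min(86L, max(16L, as.integer(score)))
    cor_time <- cfg$cor_center + cfg$cor_z_slope * z +
      stats::rnorm(1, 0, cfg$cor_sd)
    chest_acro <- cfg$chest_acro_center + cfg$chest_acro_z_slope * z +
      stats::rnorm(1, 0, cfg$chest_acro_sd)
    dlmo <- cfg$dlmo_center + cfg$dlmo_z_slope * z +
      stats::rnorm(1, 0, cfg$dlmo_sd)
    dlmo <- min(22.8, max(18.8, dlmo))          # inside the sampling evening
    dominant <- sample(names(cfg$dominant_probs), 1, prob = cfg$dominant_probs)
    amp_dom <- stats::runif(1, cfg$chest_amp_dominant[1], cfg$chest_amp_dominant[2])
    amp_min <- stats::runif(1, cfg$chest_amp_minor[1], cfg$chest_amp_minor[2])
    chest_amp24 <- switch(dominant, `24h` = amp_dom, `12h` = amp_min,
                          none = cfg$chest_amp_arrhythmic)
    chest_amp12 <- switch(dominant, `24h` = amp_min, `12h` = amp_dom,
                          none = cfg$chest_amp_arrhythmic / 2)
    chest_mesor <- stats::runif(1, cfg$chest_mesor_range[1], cfg$chest_mesor_range[2])
    # 12-h harmonic placed a quarter-cycle off the 24-h acrophase; the chest
    # bathyphase truth is the grid minimum of the resulting analytic curve
    chest_p12 <- (chest_acro %% 24) + 3
    ext <- curve_extrema(chest_amp24, chest_acro %% 24, chest_amp12, chest_p12)
    chest_bathy_daytime <- unwrap_to(ext$bathy, 11)
    cor_un <- cor_time                           # already on [12,36) scale
    bathy <- cfg$eq_intercept +
      cfg$eq_coef[["sex"]] * sex +
      cfg$eq_coef[["chronotype_score"]] * score +
      cfg$eq_coef[["center_of_rest"]] * cor_un +
      cfg$eq_coef[["chest_bathyphase"]] * chest_bathy_daytime +
      stats::rnorm(1, 0, cfg$eq_noise_sd)
    rest_dur <- max(5, stats::rnorm(1, cfg$rest_duration_mean,
                                    cfg$rest_duration_sd))
    data.frame(
      subject_id = sprintf("S%03d", i),
      sex = sex,
      age = round(stats::runif(1, cfg$age_range[1], cfg$age_range[2])),
      bmi = round(stats::rnorm(1, cfg$bmi_mean, cfg$bmi_sd), 1),
      chronotype_score = score,
      true_core_bathyphase = unwrap_to(bathy, 27.5),
      true_chest_acrophase = unwrap_to(ext$acro, 27),
      true_chest_bathyphase = chest_bathy_daytime,
      true_center_of_rest = unwrap_to(cor_time, 27),
      true_dlmo = dlmo,
      core_mesor = stats::rnorm(1, cfg$core_mesor_mean, cfg$core_mesor_sd),
      core_amp24 = stats::runif(1, cfg$core_amp24_range[1], cfg$core_amp24_range[2]),
      core_amp12 = stats::runif(1, cfg$core_amp12_range[1], cfg$core_amp12_range[2]),
      chest_mesor = chest_mesor,
      chest_amp24 = chest_amp24,
      chest_amp12 = chest_amp12,
      chest_p12 = chest_p12,
      dominant_class = dominant,
      core_noise_sd = cfg$core_noise_sd,
      chest_noise_sd = cfg$chest_noise_sd,
      rest_onset = (unwrap_to(cor_time, 27) - rest_dur / 2) %% 24,
      rest_duration = rest_dur,
      dlmo_missing = stats::runif(1) < cfg$dlmo_missing_rate,
      stringsAsFactors = FALSE
    )
  })
}

#' Re-express decimal hours near a chosen cluster center
#'
#' Adds the signed circular difference from `center` so that a set of
#' phases clustered around `center` becomes contiguous (no 24-h wrap inside
#' the cluster). Used to place nocturnal phases on \[12, 36) and daytime
#' chest bathyphases around 11 h.
#'
#' @param hours decimal hours (any representation).
#' @param center cluster center in decimal hours.
#' @return numeric hours in `(center - 12, center + 12]`.
#' @export
unwrap_to <- function(hours, center) {
  center + circular_diff(unclass(hours), center)
}

## analytic two-harmonic curve extrema on a 1-min grid (hours of day)
curve_extrema <- function(amp24, acro24, amp12, acro12) {
  t <- seq(0, 24 - 1 / 60, by = 1 / 60)
  y <- amp24 * cos(2 * pi * (t - acro24) / 24) +
    amp12 * cos(2 * pi * (t - acro12) / 12)
  list(acro = t[which.max(y)], bathy = t[which.min(y)])
}

## analytic core curve: both harmonics share their minimum at the true
## bathyphase, which makes the minimum sharp and the maximum flat -- the
## precision asymmetry seen in field recordings
core_curve <- function(truth, t_hours) {
  b <- truth$true_core_bathyphase %% 24
  truth$core_mesor +
    truth$core_amp24 * cos(2 * pi * (t_hours - (b - 12)) / 24) +
    truth$core_amp12 * cos(2 * pi * (t_hours - (b - 6)) / 12)
}

chest_curve <- function(truth, t_hours) {
  truth$chest_mesor +
    truth$chest_amp24 * cos(2 * pi * (t_hours - truth$true_chest_acrophase %% 24) / 24) +
    truth$chest_amp12 * cos(2 * pi * (t_hours - truth$chest_p12) / 12)
}

#' Generate two ingestible-pill core temperature segments
#'
#' Pills are swallowed ~24 h apart in the morning; each records until
#' gastrointestinal elimination (log-normal duration clipped to
#' `pill_duration_range` days and to the requested horizon). The first
#' `artifact_window_h` hours of each segment are contaminated with
#' food/drink ingestion artifacts (values outside 35--40 degC) at rate
#' `artifact_rate` per minute.
#'
#' @param truth one row of a [generate_cohort()] table.
#' @param days recording horizon in days (>= 2).
#' @param seed integer seed.
#' @param config a [sim_config()] list.
#' @return list with `phys_ts` elements `pill1` and `pill2`.
#' @export
generate_core_temperature <- function(truth, days = 4, seed = 1L,
                                      config = sim_config()) {
  stopifnot(days >= 2, nrow(truth) == 1)
  i <- as.integer(sub("^S", "", truth$subject_id))
  with_seed(subject_seed(seed, i, 2L), {
    start1 <- 8 + stats::runif(1, -1, 1)        # hours from origin midnight
    start2 <- start1 + 24
    dur <- function(start) {
      d <- stats::rlnorm(1, config$pill_duration_meanlog,
                         config$pill_duration_sdlog)
      d <- min(max(d, config$pill_duration_range[1]), config$pill_duration_range[2])
      min(d * 24, days * 24 - start)             # hours
    }
    make_pill <- function(start, dur_h) {
      t_h <- seq(start, start + dur_h, by = 1 / 60)
      y <- core_curve(truth, t_h %% 24) +
        stats::rnorm(length(t_h), 0, truth$core_noise_sd)
      early <- t_h - start < config$artifact_window_h
      hit <- early & stats::runif(length(t_h)) < config$artifact_rate
      if (any(hit)) {
        low <- stats::runif(sum(hit)) > 0.2
        y[hit] <- ifelse(low, stats::runif(sum(hit), 25, 34),
                         stats::runif(sum(hit), 40.5, 41.5))
      }
      phys_ts(sim_origin() + round(t_h * 3600), y, truth$subject_id, "core_temp")
    }
    list(pill1 = make_pill(start1, dur(start1)),
         pill2 = make_pill(start2, dur(start2)))
  })
}

#' Generate chest surface temperature and activity series
#'
#' Surface temperature follows the subject's dominant-period class (24-h
#' dominant, 12-h dominant, or near-arrhythmic). Activity counts come from
#' a three-regime (rest / moderately active / highly active) Markov chain
#' whose rest probability concentrates inside the subject's true rest span;
#' counts are negative-binomial per state (overdispersed, with occasional
#' bursts into the hundreds). Device-removal gaps totalling `gap_fraction`
#' of the record are cut from both channels at the same times.
#'
#' @param truth one row of a [generate_cohort()] table.
#' @param days recording duration in days (default 7).
#' @param seed integer seed.
#' @param config a [sim_config()] list.
#' @return list with `phys_ts` elements `chest_temp` and `activity`.
#' @export
generate_chest_data <- function(truth, days = 7, seed = 1L,
                                config = sim_config()) {
  stopifnot(days >= 1, nrow(truth) == 1)
  i <- as.integer(sub("^S", "", truth$subject_id))
  with_seed(subject_seed(seed, i, 3L), {
    n_min <- round(days * 1440)
    t_h <- seq(0, by = 1 / 60, length.out = n_min)
    tod <- t_h %% 24
    temp <- chest_curve(truth, tod) +
      stats::rnorm(n_min, 0, truth$chest_noise_sd)

    # rest-state target probability: smoothed in-span indicator
    center <- truth$true_center_of_rest %% 24
    half <- truth$rest_duration / 2
    d <- abs(circular_diff(tod, center))
    s <- stats::plogis((half - d) / max(config$rest_edge_softness, 1e-6))
    eps <- config$activity_regime_noise
    p1 <- (1 - eps) * s + eps / 3
    # daytime split between moderate and high activity
    p3 <- (1 - p1) * (0.2 + 0.15 * (cos(2 * pi * (tod - 17) / 24) > 0.5))
    p2 <- 1 - p1 - p3
    if (eps == 0) {
      states <- ifelse(s >= 0.5, 1L, ifelse(p3 > 0.5 * p2, 3L, 2L))
    } else {
      states <- integer(n_min)
      states[1] <- sample(1:3, 1, prob = c(p1[1], p2[1], p3[1]))
      stick <- 0.9
      u_stick <- stats::runif(n_min)
      for (t in 2:n_min) {
        if (u_stick[t] < stick) states[t] <- states[t - 1]
        else states[t] <- sample(1:3, 1, prob = c(p1[t], p2[t], p3[t]))
      }
    }
    counts <- stats::rnbinom(n_min, size = config$activity_size[states],
                             mu = config$activity_means[states])

    keep <- !gap_mask(n_min, days, config$gap_fraction)
    tm <- sim_origin() + round(t_h * 3600)
    list(
      chest_temp = phys_ts(tm[keep], temp[keep], truth$subject_id, "chest_temp"),
      activity = phys_ts(tm[keep], counts[keep], truth$subject_id, "activity")
    )
  })
}

## non-overlapping removal episodes, one per block, hitting the target
## fraction to within rounding
gap_mask <- function(n_min, days, fraction) {
  mask <- rep(FALSE, n_min)
  total <- round(n_min * fraction)
  if (total < 1) return(mask)
  k <- max(1L, round(days * 2))
  per <- diff(round(seq(0, total, length.out = k + 1)))
  block <- n_min %/% k
  for (j in seq_len(k)) {
    if (per[j] < 1) next
    lo <- (j - 1) * block
    start <- lo + sample.int(max(1, block - per[j]), 1)
    mask[start:(start + per[j] - 1)] <- TRUE
  }
  mask
}

#' Generate an evening salivary melatonin profile plus wrist lux series
#'
#' Concentration is a flat baseline before the subject's true DLMO and a
#' logistic-shaped rise after it. A configurable fraction of samples is
#' preceded (within 30 min) by a >50 lux light burst, which invalidates
#' them downstream.
#'
#' @param truth one row of a [generate_cohort()] table.
#' @param sample_times evening sampling clock times in decimal hours
#'   (default hourly 18:00--23:00).
#' @param seed integer seed.
#' @param config a [sim_config()] list.
#' @param contaminate_samples optional integer indices of samples to force
#'   light contamination on (overrides the random fraction).
#' @return list: `samples` (data.frame time_hours, concentration),
#'   `lux` (a `phys_ts`), `contaminated` (indices).
#' @export
generate_melatonin_profile <- function(truth, sample_times = 18:23, seed = 1L,
                                       config = sim_config(),
                                       contaminate_samples = NULL) {
  stopifnot(nrow(truth) == 1)
  if (any(sample_times < 18 | sample_times > 24)) {
    stop("sample times must lie within the 18:00-24:00 evening window")
  }
  i <- as.integer(sub("^S", "", truth$subject_id))
  with_seed(subject_seed(seed, i, 4L), {
    base <- stats::runif(1, config$mel_baseline_range[1], config$mel_baseline_range[2])
    amp <- stats::runif(1, config$mel_amplitude_range[1], config$mel_amplitude_range[2])
    onset <- truth$true_dlmo
    conc_at <- function(t) {
      rise <- ifelse(t > onset,
                     2 * stats::plogis((t - onset) / config$mel_rise_scale) - 1,
                     0)
      base + amp * rise
    }
    conc <- conc_at(sample_times) +
      stats::rnorm(length(sample_times), 0, config$mel_noise_sd)
    conc <- pmax(conc, 0.05)

    if (is.null(contaminate_samples)) {
      contaminated <- which(stats::runif(length(sample_times)) <
                              config$lux_contam_fraction)
    } else {
      contaminated <- as.integer(contaminate_samples)
    }
    lux_t <- seq(17.5, 23.75, by = 1 / 60)
    lux <- stats::runif(length(lux_t), 0, config$lux_dim_max)
    for (j in contaminated) {
      burst_start <- sample_times[j] - stats::runif(1, 3 / 60, 28 / 60)
      hit <- lux_t >= burst_start & lux_t <= burst_start + 3 / 60
      lux[hit] <- stats::runif(sum(hit), config$lux_burst_range[1],
                               config$lux_burst_range[2])
    }
    list(
      samples = data.frame(time_hours = sample_times, concentration = conc),
      lux = phys_ts(sim_origin() + round(lux_t * 3600), lux,
                    truth$subject_id, "lux"),
      contaminated = contaminated
    )
  })
}
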