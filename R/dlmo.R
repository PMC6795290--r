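#' Flag salivary samples invalidated by light exposure
#'
#' A sample is invalid for melatonin determination if any lux reading
#' greater than 50 occurred in the 30 minutes preceding collection,
#' i.e. in the half-open window (t - 30 min, t]. If the lux record has a
#' coverage hole over a sample's window the flag is `NA` (indeterminate).
#'
#' @param sample_times evening sampling clock times, decimal hours.
#' @param lux a `phys_ts` of wrist light readings covering the evening.
#' @param lux_limit invalidation threshold in lux (default 50).
#' @return logical vector: `TRUE` = valid, `FALSE` = invalid, `NA` =
#'   indeterminate.
#' @export
validate_samples <- function(sample_times, lux, lux_limit = 50) {
  lux_h <- hour_of_day(lux$time)
  vapply(sample_times, function(st) {
    inwin <- lux_h > st - 0.5 & lux_h <= st
    if (!any(inwin)) return(NA)
    # a hole > 5 min inside the window counts as a coverage gap
    tw <- sort(lux_h[inwin])
    gaps <- diff(c(st - 0.5, tw, st))
    if (max(gaps) > 5 / 60 + 1e-9) return(NA)
    !any(lux$value[inwin] > lux_limit)
  }, logical(1))
}

#' Select the pre-rise baseline samples of a melatonin profile
#'
#' Returns the indices of the three earliest valid samples, provided they
#' are consecutive and show no internal rise (no sample exceeding
#' `rise_factor` times the running mean of the valid samples before it
#' within the triple). Only the earliest triple is considered -- sliding
#' later would risk mistaking the saturated post-rise plateau for a
#' baseline in subjects whose melatonin onset precedes the first samples.
#' Signals insufficient baseline (returns `NULL`) when the check fails;
#' the caller then falls back to the pooled threshold.
#'
#' @param concentrations sample concentrations, pg/mL.
#' @param valid logical validity flags ([validate_samples()]); `NA` counts
#'   as invalid.
#' @param rise_factor rise detection multiplier (default 1.5).
#' @return integer indices of the 3 baseline samples, or `NULL`.
#' @export
select_baseline <- function(concentrations, valid = TRUE, rise_factor = 1.5) {
  valid <- rep_len(valid, length(concentrations)) & !is.na(valid)
  ok <- which(valid)
  if (length(ok) < 3) return(NULL)
  idx <- ok[1:3]
  if (any(diff(idx) != 1)) return(NULL)           # must be consecutive samples
  c3 <- concentrations[idx]
  no_rise <- c3[2] <= rise_factor * c3[1] &&
    c3[3] <= rise_factor * mean(c3[1:2])
  if (no_rise) idx else NULL
}

#' Individual DLMO threshold from three baseline samples
#'
#' Threshold = mean of the 3 consecutive pre-rise values plus twice their
#' sample standard deviation.
#'
#' @param baseline numeric vector of exactly 3 pre-rise concentrations.
#' @return threshold in pg/mL.
#' @export
individual_threshold <- function(baseline) {
  if (length(baseline) != 3 || anyNA(baseline)) {
    stop("insufficient baseline: need exactly 3 valid pre-rise values",
         call. = FALSE)
  }
  mean(baseline) + 2 * stats::sd(baseline)
}

#' Pooled DLMO threshold across subjects
#'
#' For subjects without adequate individual baseline data: mean plus twice
#' the sample standard deviation of the baseline values pooled across the
#' subjects that do have adequate baselines.
#'
#' @param pooled_values numeric vector of pooled baseline concentrations
#'   (>= 2 values).
#' @return threshold in pg/mL.
#' @export
pooled_threshold <- function(pooled_values) {
  pooled_values <- pooled_values[!is.na(pooled_values)]
  if (length(pooled_values) < 2) stop("need at least 2 pooled baseline values")
  mean(pooled_values) + 2 * stats::sd(pooled_values)
}

#' Compute dim light melatonin onset
#'
#' DLMO is the time at which the concentration first exceeds (strictly)
#' the threshold, linearly interpolated between the last valid sample at
#' or below the threshold and the first valid sample above it. Undefined
#' (`NA` with a `reason` attribute) when the threshold is never exceeded,
#' when the first valid sample is already above it, or when fewer than two
#' samples are valid.
#'
#' @param sample_times sampling clock times, decimal hours.
#' @param concentrations concentrations, pg/mL.
#' @param threshold threshold, pg/mL (> 0).
#' @param valid logical validity flags; default all valid.
#' @return a [clock_phase()] (scalar), or `NA` with attribute `reason`.
#' @export
compute_dlmo <- function(sample_times, concentrations, threshold,
                         valid = TRUE) {
  stopifnot(threshold > 0)
  valid <- rep_len(valid, length(sample_times)) & !is.na(valid)
  undefined <- function(reason) {
    out <- clock_phase(NA_real_); attr(out, "reason") <- reason; out
  }
  t_v <- sample_times[valid]; c_v <- concentrations[valid]
  if (length(t_v) < 2) return(undefined("fewer than 2 valid samples"))
  above <- c_v > threshold
  if (!any(above)) return(undefined("threshold never exceeded"))
  first_above <- which(above)[1]
  if (first_above == 1) return(undefined("first valid sample already above threshold"))
  i0 <- first_above - 1L
  t0 <- t_v[i0]; t1 <- t_v[first_above]
  c0 <- c_v[i0]; c1 <- c_v[first_above]
  clock_phase(t0 + (threshold - c0) / (c1 - c0) * (t1 - t0))
}

#' Full DLMO determination for one subject
#'
#' Applies the light-validity rule, tries the individual baseline
#' threshold, falls back to a supplied pooled threshold when the baseline
#' is inadequate, and interpolates the onset.
#'
#' @param sample_times,concentrations the evening profile.
#' @param lux a lux `phys_ts`, or `NULL` to accept all samples as valid.
#' @param pooled pooled threshold to fall back on, or `NA`.
#' @return list: `dlmo` ([clock_phase()] or `NA`), `threshold`,
#'   `threshold_kind` ("individual", "pooled" or "none"), `valid` flags,
#'   `baseline_idx`.
#' @export
dlmo_for_subject <- function(sample_times, concentrations, lux = NULL,
                             pooled = NA_real_) {
  valid <- if (is.null(lux)) rep(TRUE, length(sample_times))
  else validate_samples(sample_times, lux)
  base_idx <- select_baseline(concentrations, valid)
  if (!is.null(base_idx)) {
    thr <- individual_threshold(concentrations[base_idx])
    kind <- "individual"
  } else if (!is.na(pooled)) {
    thr <- pooled; kind <- "pooled"
  } else {
    out <- clock_phase(NA_real_); attr(out, "reason") <- "no usable threshold"
    return(list(dlmo = out, threshold = NA_real_, threshold_kind = "none",
                valid = valid, baseline_idx = NULL))
  }
  list(dlmo = compute_dlmo(sample_times, concentrations, thr, valid),
       threshold = thr, threshold_kind = kind, valid = valid,
       baseline_idx = base_idx)
}
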