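#' Stitch the two ingestible-pill segments into one core temperature series
#'
#' The first pill's record is used until its elimination (its last sample);
#' the second pill's record is used strictly thereafter, with any
#' overlapping portion of the second segment discarded.
#'
#' @param pill1,pill2 `phys_ts` core-temperature series from the same
#'   subject; `pill1` must start no later than `pill2`.
#' @return one stitched `phys_ts`.
#' @export
stitch_pills <- function(pill1, pill2) {
  if (!identical(attr(pill1, "subject_id"), attr(pill2, "subject_id"))) {
    stop("pills belong to different subjects")
  }
  if (nrow(pill2) == 0) return(pill1)
  if (nrow(pill1) == 0) return(pill2)
  if (pill1$time[1] == pill2$time[1]) {
    stop("validation error: pill segments have identical start times")
  }
  if (pill1$time[1] > pill2$time[1]) stop("pill1 must start before pill2")
  cut <- pill1$time[nrow(pill1)]
  after <- pill2$time > cut
  gap_h <- as.numeric(difftime(pill2$time[after][1], cut, units = "hours"))
  if (!any(after)) return(pill1)
  if (!is.na(gap_h) && gap_h > 24) {
    warning(sprintf("gap of %.1f h between pill segments; stitching anyway",
                    gap_h))
  }
  ts_like(pill1, c(pill1$time, pill2$time[after]),
          c(pill1$value, pill2$value[after]))
}

#' Remove ingestion artifacts from a core temperature segment
#'
#' Food or drink ingestion distorts the pill reading in the first hours
#' after swallowing. Within the first `window_h` hours of each recording
#' segment (segments separated by gaps > 6 h), samples outside
#' `plausible_range` are deleted. The number removed is attached as
#' attribute `n_removed` and reported via `message()`.
#'
#' @param series a core-temperature `phys_ts`.
#' @param window_h artifact window after each segment start, hours
#'   (default 3).
#' @param plausible_range physiological range in degC, default c(35, 40).
#' @return the cleaned `phys_ts` with attribute `n_removed`.
#' @export
remove_ingestion_artifacts <- function(series, window_h = 3,
                                       plausible_range = c(35, 40)) {
  if (nrow(series) == 0) return(series)
  tnum <- as.numeric(series$time)
  seg <- cumsum(c(TRUE, diff(tnum) > 6 * 3600))
  seg_start <- ave(tnum, seg, FUN = min)
  early <- tnum - seg_start < window_h * 3600
  bad <- early & (series$value < plausible_range[1] |
                    series$value > plausible_range[2])
  for (s in unique(seg)) {
    in_seg <- seg == s
    if (sum(bad & in_seg) > 0.5 * sum(in_seg)) {
      warning(sprintf("more than half of segment %d removed as artifacts", s))
    }
  }
  out <- ts_like(series, series$time[!bad], series$value[!bad])
  attr(out, "n_removed") <- sum(bad)
  if (sum(bad) > 0) message(sprintf("removed %d ingestion artifact(s)", sum(bad)))
  out
}

#' Aggregate a minute-level series into 5-minute means
#'
#' Bins are left-closed and aligned to the clock (00:00, 00:05, ...); the
#' bin value is the mean of the samples present and empty bins are simply
#' absent (never zero-filled). The bin is timestamped at its left edge.
#'
#' @param series a `phys_ts`.
#' @return a `phys_ts` on the 5-minute grid.
#' @export
aggregate_5min <- function(series) {
  if (nrow(series) == 0) return(series)
  bin <- as.numeric(series$time) %/% 300 * 300
  agg <- tapply(series$value, bin, mean)
  tm <- as.POSIXct(as.numeric(names(agg)), origin = "1970-01-01", tz = "UTC")
  ts_like(series, tm, as.numeric(agg))
}

#' Centered one-hour moving average
#'
#' Each sample is replaced by the mean of the samples within the
#' one-hour window \[t - 30 min, t + 30 min) (12 bins on a full 5-minute
#' grid); at the edges and across gaps only the samples actually present
#' are averaged.
#'
#' @param series a `phys_ts` (typically 5-min aggregated).
#' @param window_min window width in minutes (default 60).
#' @return smoothed `phys_ts` on the same timestamps.
#' @export
moving_average <- function(series, window_min = 60) {
  n <- nrow(series)
  if (n == 0) return(series)
  tnum <- as.numeric(series$time)
  half <- window_min / 2 * 60
  # two-pointer sweep over the sorted timestamps
  out <- numeric(n)
  lo <- 1L; hi <- 0L; s <- 0; cnt <- 0L
  for (k in seq_len(n)) {
    while (hi < n && tnum[hi + 1L] < tnum[k] + half) {
      hi <- hi + 1L; s <- s + series$value[hi]; cnt <- cnt + 1L
    }
    while (tnum[lo] < tnum[k] - half) {
      s <- s - series$value[lo]; cnt <- cnt - 1L; lo <- lo + 1L
    }
    out[k] <- s / cnt
  }
  ts_like(series, series$time, out)
}

#' Averaged 24-hour profile on the 5-minute clock grid
#'
#' Collapses a multi-day series onto minute-of-day: each 5-min clock bin is
#' the mean across days of the values observed in that bin. Bins with no
#' data carry `NA` (flagged, not zero-filled).
#'
#' @param series a smoothed 5-min `phys_ts` spanning at least 24 h.
#' @return an object of class `daily_profile`: data.frame with `minute`
#'   (0, 5, ..., 1435), `value`, `n` (contributing bins), and attribute
#'   `channel`.
#' @export
average_24h_profile <- function(series) {
  if (nrow(series) < 2) stop("series too short for a 24-h profile")
  span_h <- as.numeric(difftime(series$time[nrow(series)], series$time[1],
                                units = "hours"))
  if (span_h < 24) stop("need at least 24 h of data for an averaged profile")
  mod <- (as.numeric(series$time) %/% 300 * 300) %% 86400 / 60
  grid <- seq(0, 1435, by = 5)
  val <- tapply(series$value, factor(mod, levels = grid), mean)
  n <- tapply(series$value, factor(mod, levels = grid), length)
  out <- data.frame(minute = grid, value = as.numeric(val),
                    n = ifelse(is.na(n), 0L, as.integer(n)))
  structure(out, channel = attr(series, "channel"),
            subject_id = attr(series, "subject_id"),
            class = c("daily_profile", "data.frame"))
}

#' Standard preprocessing chain: 5-min aggregate, 1-h smooth, 24-h profile
#'
#' @param series a minute-level `phys_ts`.
#' @return a `daily_profile`.
#' @export
preprocess_profile <- function(series) {
  average_24h_profile(moving_average(aggregate_5min(series)))
}

#' Lagged Pearson correlation between two overlapping series
#'
#' Aligns both series on the minute grid over their overlap (which must be
#' at least 24 h) and computes the Pearson correlation at every integer
#' minute lag in `[-max_lag, max_lag]`. The correlation at lag L pairs
#' `a(t)` with `b(t - L)`, so if `b` is a delayed copy of `a` the best lag
#' is negative. Ties are broken toward lag 0.
#'
#' @param a,b `phys_ts` objects.
#' @param max_lag maximum absolute lag in minutes (default 30).
#' @return list: `best_lag` (minutes), `best_r`, and data.frame `by_lag`.
#' @export
lag_correlation <- function(a, b, max_lag = 30) {
  ta <- round(as.numeric(a$time) / 60); tb <- round(as.numeric(b$time) / 60)
  lo <- max(min(ta), min(tb)); hi <- min(max(ta), max(tb))
  if (hi - lo < 1440) stop("overlap shorter than 24 h")
  grid <- lo:hi
  va <- rep(NA_real_, length(grid)); vb <- rep(NA_real_, length(grid))
  va[match(ta, grid, nomatch = 0)] <- a$value[ta %in% grid]
  vb[match(tb, grid, nomatch = 0)] <- b$value[tb %in% grid]
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(L) {
    # pair a(t) with b(t - L)
    if (L >= 0) {
      x <- va[(1 + L):length(grid)]; y <- vb[1:(length(grid) - L)]
    } else {
      x <- va[1:(length(grid) + L)]; y <- vb[(1 - L):length(grid)]
    }
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  best <- which(r == max(r, na.rm = TRUE))
  best <- best[which.min(abs(lags[best]))]       # ties toward 0
  list(best_lag = lags[best], best_r = r[best],
       by_lag = data.frame(lag = lags, r = r))
}
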