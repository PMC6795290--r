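#' Clock phases on the unwrapped [12, 36) window
#'
#' Circadian phase markers in this package (bathyphase, acrophase, DLMO,
#' center-of-rest) are clock times of day. Nocturnal phases cluster around
#' 03:00--04:00, right next to the midnight wrap point, so naive decimal
#' hours in \[0, 24) would split a tight cluster into values near 0 and values
#' near 24 and wreck any downstream regression. A `clock_phase` therefore
#' stores decimal hours on the window \[12, 36) anchored at the prior noon:
#' 17:40 stays 17.667, while 03:30 becomes 27.5. All observed nocturnal
#' phases are interior to the window and ordinary linear arithmetic applies
#' within a cluster.
#'
#' @param hours numeric vector of decimal hours (any real value; wrapped
#'   modulo 24 into \[12, 36)). `NA` is propagated.
#' @return a numeric vector of class `clock_phase` with values in \[12, 36).
#' @examples
#' clock_phase(3.5)            # 27.5
#' clock_phase(c(12, 17.667))  # 12, 17.667
#' @export
clock_phase <- function(hours) {
  stopifnot(is.numeric(hours))
  out <- ((hours - 12) %% 24) + 12
  structure(out, class = "clock_phase")
}

#' Convert a time of day to a clock phase
#'
#' @param hour hour of day (0--23), or a string `"HH:MM"` in which case
#'   `minute` is ignored.
#' @param minute minute (0--59), default 0.
#' @return a [clock_phase()] in \[12, 36).
#' @examples
#' to_clock_phase(3, 30)   # 27.5
#' to_clock_phase("17:40") # 17.667
#' @export
to_clock_phase <- function(hour, minute = 0) {
  if (is.character(hour)) {
    parts <- strsplit(hour, ":", fixed = TRUE)
    hh <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    mm <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 0,
                 numeric(1))
    hour <- hh; minute <- mm
  }
  if (any(!is.na(hour) & (hour < 0 | hour >= 24)) ||
      any(!is.na(minute) & (minute < 0 | minute >= 60))) {
    stop("time of day out of range (hour in [0,24), minute in [0,60))")
  }
  clock_phase(hour + minute / 60)
}

#' @export
print.clock_phase <- function(x, ...) {
  cat("<clock_phase> hours on [12, 36):\n")
  print(unclass(x), ...)
  clk <- unclass(x) %% 24
  cat("as clock time:", paste(format_clock(clk), collapse = " "), "\n")
  invisible(x)
}

#' Format decimal hours as HH:MM clock time
#' @param hours numeric decimal hours (wrapped modulo 24).
#' @return character vector `"HH:MM"`.
#' @export
format_clock <- function(hours) {
  hours <- unclass(hours) %% 24
  mins <- round(hours * 60)
  sprintf("%02d:%02d", (mins %/% 60) %% 24, mins %% 60)
}

#' Circular distance between clock phases
#'
#' Shortest distance around the 24-h circle; always in \[0, 12\] hours.
#'
#' @param a,b numeric decimal hours (any representation; taken modulo 24).
#' @return numeric vector of distances in hours.
#' @examples
#' circular_distance(23.9, 24.1) # 0.2
#' @export
circular_distance <- function(a, b) {
  d <- abs((unclass(a) - unclass(b)) %% 24)
  pmin(d, 24 - d)
}

#' Signed circular difference a - b on (-12, 12]
#'
#' Positive means `a` is later than `b` on the shortest arc.
#'
#' @param a,b numeric decimal hours.
#' @return signed difference in hours, in (-12, 12].
#' @export
circular_diff <- function(a, b) {
  d <- (unclass(a) - unclass(b)) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Circular mean of clock times
#'
#' Resultant-vector mean of times of day; weights optional. Used for the
#' center-of-rest time (gravity center of the inactive-state probability
#' profile) where the mass typically straddles midnight.
#'
#' @param hours numeric decimal hours.
#' @param w non-negative weights, recycled to `length(hours)`.
#' @return a [clock_phase()]; `NA` if total weight is zero.
#' @export
circular_mean_hours <- function(hours, w = 1) {
  w <- rep_len(w, length(hours))
  keep <- !is.na(hours) & !is.na(w)
  hours <- hours[keep]; w <- w[keep]
  if (length(hours) == 0L || sum(w) <= 0) return(clock_phase(NA_real_))
  theta <- unclass(hours) / 24 * 2 * pi
  s <- sum(w * sin(theta)); c <- sum(w * cos(theta))
  if (s == 0 && c == 0) return(clock_phase(NA_real_))
  clock_phase((atan2(s, c) / (2 * pi) * 24) %% 24)
}
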