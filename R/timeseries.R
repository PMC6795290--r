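#' Minute-level physiological time series
#'
#' The shared container for every recorded channel: core body temperature
#' from ingestible pills, chest surface temperature, activity counts and
#' light exposure from the chest/wrist sensors, and evening salivary
#' melatonin. A series is a data frame with columns `time` (POSIXct, minute
#' resolution, strictly increasing; gaps permitted and never imputed here),
#' `value` (numeric) plus attributes `subject_id`, `channel` and `unit`.
#'
#' @param time POSIXct vector, strictly increasing.
#' @param value numeric vector, same length.
#' @param subject_id subject identifier string.
#' @param channel channel name, e.g. `"core_temp"`, `"chest_temp"`,
#'   `"activity"`, `"lux"`, `"melatonin"`.
#' @param unit unit tag; one of `"degC"`, `"counts_per_min"`, `"lux"`,
#'   `"pg_per_mL"`. Defaults to the conventional unit for `channel`.
#' @return an object of class `phys_ts` (a data.frame).
#' @export
phys_ts <- function(time, value, subject_id, channel,
                    unit = default_unit(channel)) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  if (length(time) != length(value)) stop("time/value length mismatch")
  if (length(time) > 1L) {
    d <- diff(as.numeric(time))
    if (any(d <= 0)) {
      stop(sprintf("timestamps not strictly increasing at row %d",
                   which(d <= 0)[1] + 1L))
    }
  }
  unit <- match.arg(unit, c("degC", "counts_per_min", "lux", "pg_per_mL"))
  structure(
    data.frame(time = time, value = as.numeric(value)),
    subject_id = as.character(subject_id),
    channel = as.character(channel),
    unit = unit,
    class = c("phys_ts", "data.frame")
  )
}

default_unit <- function(channel) {
  switch(channel,
         core_temp = , chest_temp = "degC",
         activity = "counts_per_min",
         lux = "lux",
         melatonin = "pg_per_mL",
         "degC")
}

#' @export
print.phys_ts <- function(x, ...) {
  cat(sprintf("<phys_ts> subject %s, channel %s [%s], %d samples",
              attr(x, "subject_id"), attr(x, "channel"), attr(x, "unit"),
              nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %s to %s", format(x$time[1]), format(x$time[nrow(x)])))
  }
  cat("\n")
  invisible(x)
}

ts_meta <- function(x) {
  list(subject_id = attr(x, "subject_id"), channel = attr(x, "channel"),
       unit = attr(x, "unit"))
}

## rebuild a phys_ts with the same metadata but new rows
ts_like <- function(x, time, value) {
  phys_ts(time, value, attr(x, "subject_id"), attr(x, "channel"),
          attr(x, "unit"))
}

#' Concatenate two series of the same subject, channel and unit
#' @param a,b `phys_ts` objects with identical metadata; `b` strictly later.
#' @return combined `phys_ts`.
#' @export
ts_concat <- function(a, b) {
  if (!identical(attr(a, "unit"), attr(b, "unit"))) {
    stop("refusing to concatenate series with different unit tags")
  }
  if (!identical(attr(a, "subject_id"), attr(b, "subject_id"))) {
    stop("refusing to concatenate series from different subjects")
  }
  ts_like(a, c(a$time, b$time), c(a$value, b$value))
}

#' Read a time series from delimited text
#'
#' Expects a CSV (UTF-8) with header columns `timestamp` (ISO-8601),
#' `value` and `subject_id`; an optional `channel` column is used to filter
#' when several channels share one file. Rows whose timestamp does not parse
#' are reported via a warning and dropped; non-monotone timestamps are an
#' error naming the first offending row.
#'
#' @param path file path.
#' @param channel channel name to select (and to tag the result with).
#' @param unit unit tag; defaults to the channel's conventional unit.
#' @return a [phys_ts()].
#' @export
read_timeseries <- function(path, channel, unit = default_unit(channel)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "value", "subject_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("format error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  }
  if ("channel" %in% names(df)) df <- df[df$channel == channel, , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("no rows for channel %s in %s", channel, path))
  tm <- parse_iso_times(df$timestamp)
  bad <- is.na(tm) & !is.na(df$timestamp)
  if (any(bad)) {
    warning(sprintf("%d row(s) with unparseable timestamps dropped", sum(bad)))
    df <- df[!bad, , drop = FALSE]; tm <- tm[!bad]
  }
  if (anyDuplicated(tm) || is.unsorted(tm, strictly = TRUE)) {
    d <- diff(as.numeric(tm))
    stop(sprintf("validation error: timestamps not strictly increasing at row %d",
                 which(d <= 0)[1] + 1L))
  }
  sid <- unique(df$subject_id)
  if (length(sid) != 1) stop("file mixes multiple subject_ids")
  phys_ts(tm, df$value, sid, channel, unit)
}

#' Write a time series as delimited text
#'
#' Inverse of [read_timeseries()]: a round trip reproduces timestamps exactly
#' and values to better than 1e-9.
#'
#' @param x a `phys_ts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  df <- data.frame(
    timestamp = format(x$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = sprintf("%.10g", x$value),
    subject_id = attr(x, "subject_id"),
    channel = attr(x, "channel")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## lenient ISO-8601 parser: tries each format, NA where none matches
parse_iso_times <- function(s) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(s[miss], f, tz = "UTC"))
  }
  out
}

## decimal hours since midnight of the day of each timestamp
hour_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

## minutes since an arbitrary origin (first sample), for lag work
minutes_since_start <- function(x) {
  as.numeric(difftime(x$time, x$time[1], units = "mins"))
}
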