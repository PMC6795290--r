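#' Two-harmonic cosinor regression
#'
#' Fits, by ordinary least squares, the rhythm model
#' \deqn{y(t) = M + a_1 cos(2\pi t/T_1) + b_1 sin(2\pi t/T_1)
#'            + a_2 cos(2\pi t/T_2) + b_2 sin(2\pi t/T_2) + e(t)}
#' with fixed periods T1 = 12 h and T2 = 24 h, to an averaged 24-h profile
#' or to a raw series. M is the mesor (mean level of the fitted curve);
#' the acrophase and bathyphase are the clock times of the maximum and
#' minimum of the fitted curve on a 1-minute grid.
#'
#' @param x a `daily_profile` or a `phys_ts`.
#' @param periods harmonic periods in hours (fixed at c(12, 24)).
#' @return an object of class `cosinor_fit`: list with `M`, `a1`, `b1`,
#'   `a2`, `b2`, `coef` (named vector), `residuals`, `t_hours` (hours of
#'   day of the input points), `y`, `fitted`, `acrophase` and `bathyphase`
#'   ([clock_phase()]; `NA` with attribute `reason` when the harmonic
#'   amplitude is zero), `range` (peak-to-trough of the fitted curve).
#' @export
fit_cosinor <- function(x, periods = c(12, 24)) {
  if (!identical(sort(periods), c(12, 24))) {
    stop("this model is fixed at 12-h and 24-h harmonics")
  }
  if (inherits(x, "daily_profile")) {
    ok <- !is.na(x$value)
    t_h <- x$minute[ok] / 60
    y <- x$value[ok]
  } else if (inherits(x, "phys_ts")) {
    t_h <- hour_of_day(x$time)
    y <- x$value
  } else stop("x must be a daily_profile or phys_ts")
  if (length(unique(round(t_h * 60))) < 8) {
    stop("need at least 8 distinct time points")
  }
  X <- cosinor_design(t_h)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient cosinor design (degenerate sampling times)")
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  fit <- list(
    M = unname(beta[1]),
    a1 = unname(beta[2]), b1 = unname(beta[3]),
    a2 = unname(beta[4]), b2 = unname(beta[5]),
    coef = stats::setNames(beta, c("M", "a1", "b1", "a2", "b2")),
    t_hours = t_h, y = y, fitted = fitted,
    residuals = y - fitted
  )
  ph <- extract_phases(fit)
  fit$acrophase <- ph$acrophase
  fit$bathyphase <- ph$bathyphase
  fit$range <- ph$range
  class(fit) <- "cosinor_fit"
  fit
}

## design matrix {1, cos12, sin12, cos24, sin24}; t in decimal hours
cosinor_design <- function(t_h) {
  cbind(1, cos(2 * pi * t_h / 12), sin(2 * pi * t_h / 12),
        cos(2 * pi * t_h / 24), sin(2 * pi * t_h / 24))
}

## fitted curve evaluated on the 1-min grid, given a coefficient vector
cosinor_grid <- local({
  grid_t <- seq(0, 24 - 1 / 60, by = 1 / 60)
  G <- NULL
  function(beta) {
    if (is.null(G)) G <<- cosinor_design(grid_t)
    drop(G %*% beta)
  }
})

grid_hours <- function() seq(0, 24 - 1 / 60, by = 1 / 60)

#' Extract acrophase and bathyphase from a cosinor fit
#'
#' The overall acrophase is the clock time of the maximal fitted value on
#' a 1-minute grid over \[0, 24); the bathyphase the time of the minimal
#' value. Ties are broken toward the earliest clock time. If the total
#' harmonic amplitude is zero the phases are undefined (`NA` with attribute
#' `reason = "zero amplitude"`).
#'
#' @param fit a `cosinor_fit` (or a list with elements a1, b1, a2, b2, M).
#' @return list with `acrophase`, `bathyphase` ([clock_phase()]) and
#'   `range` (fitted peak-to-trough).
#' @export
extract_phases <- function(fit) {
  amp <- sqrt(fit$a1^2 + fit$b1^2 + fit$a2^2 + fit$b2^2)
  if (amp < 1e-9 * max(1, abs(fit$M))) {
    und <- clock_phase(NA_real_)
    attr(und, "reason") <- "zero amplitude"
    return(list(acrophase = und, bathyphase = und, range = 0))
  }
  beta <- c(fit$M, fit$a1, fit$b1, fit$a2, fit$b2)
  yhat <- cosinor_grid(beta)
  tg <- grid_hours()
  list(acrophase = clock_phase(tg[which.max(yhat)]),
       bathyphase = clock_phase(tg[which.min(yhat)]),
       range = max(yhat) - min(yhat))
}

#' Residual-bootstrap circular confidence intervals for the phases
#'
#' Resamples the fit's residuals i.i.d. onto the fitted values, refits the
#' cosinor on the same design, and collects the bootstrap acrophases and
#' bathyphases. The CI is the central `level` mass of the signed circular
#' differences from the point estimate, re-centered on it (and always
#' containing it). Deterministic given `seed`.
#'
#' @param fit a `cosinor_fit`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.90).
#' @param seed integer seed.
#' @return list with `acrophase_ci`, `bathyphase_ci` (each `c(lo, hi)` on
#'   the unwrapped hour axis of the point estimate), widths in hours, and
#'   the bootstrap phase draws.
#' @export
bootstrap_phase_ci <- function(fit, n_boot = 1000, level = 0.90, seed = 1L) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (n_boot < 50) warning("n_boot < 50: confidence intervals will be unstable")
  X <- cosinor_design(fit$t_hours)
  qrX <- qr(X)
  n <- length(fit$residuals)
  tg <- grid_hours()
  G <- cosinor_design(tg)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    Ystar <- fit$fitted + matrix(fit$residuals[idx], nrow = n)
    B <- qr.coef(qrX, Ystar)                      # 5 x n_boot
    curves <- G %*% B                             # 1440 x n_boot
    acro_b <- tg[max.col(t(curves), ties.method = "first")]
    bathy_b <- tg[max.col(t(-curves), ties.method = "first")]
  })
  ci_of <- function(boot, point) {
    d <- circular_diff(boot, point)
    qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- min(qs[1], 0); hi <- max(qs[2], 0)      # anchored to the estimate
    c(unclass(point) + lo, unclass(point) + hi)
  }
  acro_ci <- ci_of(acro_b, fit$acrophase)
  bathy_ci <- ci_of(bathy_b, fit$bathyphase)
  list(acrophase_ci = acro_ci, bathyphase_ci = bathy_ci,
       acrophase_width = diff(acro_ci), bathyphase_width = diff(bathy_ci),
       boot_acrophase = acro_b, boot_bathyphase = bathy_b,
       level = level, n_boot = n_boot)
}

#' Classify the dominant periodic component of a series
#'
#' Compares the fitted harmonic amplitude at 24 h and at 12 h against a
#' permutation null in which each recorded day is independently circularly
#' shifted in time (destroying day-to-day phase alignment while keeping
#' each day's values and autocorrelation). A period is significant when
#' its observed amplitude exceeds the `1 - alpha` quantile of its null;
#' the dominant period is the significant one with the larger amplitude,
#' or `"none"` when neither is significant.
#'
#' @param series a `phys_ts` spanning at least 3 days.
#' @param seed integer seed for the permutation draws.
#' @param n_perm number of per-day circular-shift permutations (default 99).
#' @param alpha per-period significance level (default 0.01; two periods
#'   are screened, so the family-wise false-alarm rate on arrhythmic data
#'   stays around 2%).
#' @return list: `dominant` in `c("24h", "12h", "none")`, observed
#'   amplitudes `amp24`, `amp12`, and the null quantiles.
#' @export
classify_dominant_period <- function(series, seed = 1L, n_perm = 99,
                                     alpha = 0.01) {
  span_h <- as.numeric(difftime(series$time[nrow(series)], series$time[1],
                                units = "hours"))
  if (span_h < 72) stop("need at least 3 days of data")
  tod <- hour_of_day(series$time)
  day <- as.numeric(series$time) %/% 86400
  y <- series$value
  amps <- function(t_h, v) {
    X <- cosinor_design(t_h)
    beta <- qr.coef(qr(X), v)
    c(amp24 = sqrt(beta[4]^2 + beta[5]^2), amp12 = sqrt(beta[2]^2 + beta[3]^2))
  }
  obs <- amps(tod, y)
  days <- unique(day)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      shift <- stats::runif(length(days), 0, 24)
      t_shift <- (tod + shift[match(day, days)]) %% 24
      amps(t_shift, y)
    }, numeric(2))
  })
  q24 <- stats::quantile(null[1, ], 1 - alpha, names = FALSE)
  q12 <- stats::quantile(null[2, ], 1 - alpha, names = FALSE)
  sig <- c(`24h` = obs[1] > q24, `12h` = obs[2] > q12)
  dominant <- if (!any(sig)) "none"
  else c("24h", "12h")[sig][which.max(obs[sig])]
  list(dominant = dominant, amp24 = unname(obs[1]), amp12 = unname(obs[2]),
       null_q24 = q24, null_q12 = q12, alpha = alpha)
}
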