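#' Fit a three-state harmonic hidden Markov model to activity counts
#'
#' Minute-level activity counts are log-transformed (`log(1 + x)`) and
#' modelled with Gaussian emissions in three latent states -- inactive/rest,
#' moderately active and highly active -- ordered by ascending emission
#' mean. The transition probabilities vary over the 24-h day: each row of
#' transition logits is a baseline plus `n_harmonics` sine/cosine pairs at
#' the 24-h period (and its harmonics) evaluated at the clock time of the
#' current minute, which lets the rest state recruit at night and release
#' in the morning. Estimation is EM (Baum-Welch with a weighted multinomial
#' logistic M-step for the transition parameters), with seeded random
#' restarts; the best likelihood is kept and states are relabelled by
#' emission mean. Missing minutes are marginalised out of the likelihood.
#'
#' @param activity a minute-level `phys_ts` of counts spanning >= 2 days.
#' @param n_harmonics harmonics of the 24-h period on the transition
#'   logits (default 1).
#' @param seed integer seed (restart initialisation).
#' @param n_restarts random EM restarts (default 3).
#' @param max_iter maximum EM iterations per restart (default 50).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @return an object of class `harmonic_hmm`: emission means/SDs (on the
#'   log scale) per state, initial distribution, transition parameters
#'   (per-row baseline and harmonic coefficients), the 1440-minute
#'   transition array, log-likelihood, EM trace, convergence flag.
#' @export
fit_harmonic_hmm <- function(activity, n_harmonics = 1, seed = 1L,
                             n_restarts = 3, max_iter = 50, tol = 1e-6) {
  span_h <- as.numeric(difftime(activity$time[nrow(activity)],
                                activity$time[1], units = "hours"))
  if (span_h < 48) stop("need at least 2 days of activity data")
  if (stats::sd(activity$value, na.rm = TRUE) < 1e-8) {
    stop("degenerate fit: activity series is constant")
  }
  g <- minute_grid(activity)
  x <- g$x; minute <- g$minute
  K <- 3L
  runs <- lapply(seq_len(n_restarts), function(r) {
    em_run(x, minute, K, n_harmonics, subject_seed(seed, r, 5L),
           max_iter, tol, jitter = (r > 1))
  })
  ll <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which.max(ll)]]
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best fit found")
  }
  best <- relabel_by_mean(best)
  best$activity_minute <- minute
  best$logx <- x
  best$n_harmonics <- n_harmonics
  best$restart_logliks <- ll
  class(best) <- "harmonic_hmm"
  best
}

## regularise a gappy series onto the full minute grid; gaps become NA
## (marginalised out of the likelihood by a zero emission log-density row)
minute_grid <- function(activity) {
  tmin <- round(as.numeric(activity$time) / 60)
  grid <- tmin[1]:tmin[length(tmin)]
  x <- rep(NA_real_, length(grid))
  x[match(tmin, grid)] <- log1p(activity$value)
  list(x = x, minute = as.integer(grid %% 1440))
}

## harmonic covariate matrix for minute-of-day m: (1, cos, sin, ...)
harmonic_basis <- function(minutes, n_harmonics) {
  out <- matrix(1, length(minutes), 1 + 2 * n_harmonics)
  for (h in seq_len(n_harmonics)) {
    w <- 2 * pi * h * minutes / 1440
    out[, 2 * h] <- cos(w)
    out[, 2 * h + 1] <- sin(w)
  }
  out
}

## build the K x K x 1440 transition array from per-row logit parameters.
## theta: list of K matrices, each (K-1) x (1 + 2H): logits of moving to
## the other states (in index order), self-transition as reference 0.
transition_array <- function(theta, K, n_harmonics) {
  Xb <- harmonic_basis(0:1439, n_harmonics)          # 1440 x p
  arr <- array(0, c(K, K, 1440))
  for (i in seq_len(K)) {
    eta <- matrix(0, 1440, K)
    others <- setdiff(seq_len(K), i)
    eta[, others] <- Xb %*% t(theta[[i]])
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta); p <- p / rowSums(p)
    arr[i, , ] <- t(p)
  }
  arr
}

em_run <- function(x, minute, K, n_harmonics, seed, max_iter, tol, jitter) {
  obs <- !is.na(x)
  qs <- stats::quantile(x[obs], c(1, 3, 5) / 6, names = FALSE)
  p <- 1 + 2 * n_harmonics
  with_seed(seed, {
    mu <- qs + if (jitter) stats::rnorm(K, 0, 0.3) else 0
    sigma <- rep(stats::sd(x[obs]) / 2, K)
    theta <- lapply(seq_len(K), function(i) {
      m <- matrix(0, K - 1, p)
      m[, 1] <- -3 + if (jitter) stats::rnorm(K - 1, 0, 0.5) else 0
      m
    })
    init <- rep(1 / K, K)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ld <- matrix(0, length(x), K)
      for (k in seq_len(K)) {
        ld[obs, k] <- stats::dnorm(x[obs], mu[k], sigma[k], log = TRUE)
      }
      arr <- transition_array(theta, K, n_harmonics)
      e <- fb_pass(ld, init, as.numeric(arr), minute)
      trace <- c(trace, e$loglik)
      if (it > 1 && abs(e$loglik - trace[it - 1]) <
          tol * (abs(trace[it - 1]) + 1)) {
        converged <- TRUE
        gamma <- e$gamma
        break
      }
      gamma <- e$gamma
      # emissions (missing rows contribute nothing)
      for (k in seq_len(K)) {
        w <- gamma[obs, k]
        mu[k] <- sum(w * x[obs]) / sum(w)
        sigma[k] <- sqrt(sum(w * (x[obs] - mu[k])^2) / sum(w))
        sigma[k] <- max(sigma[k], 0.05)
      }
      init <- gamma[1, ]
      # transitions: weighted multinomial logit per row
      theta <- lapply(seq_len(K), function(i) {
        fit_transition_row(e$xi_by_minute, i, K, n_harmonics, theta[[i]])
      })
    }
    list(means = expm1(mu), log_means = mu, log_sds = sigma, init = init,
         theta = theta, trans = transition_array(theta, K, n_harmonics),
         loglik = trace[length(trace)], trace = trace,
         converged = converged, gamma = gamma)
  })
}

## maximise sum_m sum_j xi[m,i,j] log softmax_j(eta_ij(m)) over the row-i
## logit parameters (self-transition is the reference category)
fit_transition_row <- function(xi_by_minute, i, K, n_harmonics, start) {
  Xb <- harmonic_basis(0:1439, n_harmonics)
  p <- ncol(Xb)
  counts <- xi_by_minute[, i + K * (seq_len(K) - 1)]    # 1440 x K (to-states)
  keep <- rowSums(counts) > 0
  Xb <- Xb[keep, , drop = FALSE]; counts <- counts[keep, , drop = FALSE]
  others <- setdiff(seq_len(K), i)
  obj <- function(par) {
    th <- matrix(par, K - 1, p)
    eta <- matrix(0, nrow(Xb), K)
    eta[, others] <- Xb %*% t(th)
    m <- apply(eta, 1, max)
    logZ <- m + log(rowSums(exp(eta - m)))
    -sum(counts * (eta - logZ))
  }
  grad <- function(par) {
    th <- matrix(par, K - 1, p)
    eta <- matrix(0, nrow(Xb), K)
    eta[, others] <- Xb %*% t(th)
    m <- apply(eta, 1, max)
    pr <- exp(eta - m); pr <- pr / rowSums(pr)
    resid <- counts - rowSums(counts) * pr              # 1440 x K
    -as.numeric(t(resid[, others, drop = FALSE]) %*% Xb)
  }
  fit <- stats::optim(as.numeric(start), obj, grad, method = "BFGS",
                      control = list(maxit = 100))
  matrix(fit$par, K - 1, p)
}

## order states by ascending emission mean; state 1 is inactive/rest
relabel_by_mean <- function(run) {
  ord <- order(run$log_means)
  if (identical(ord, seq_along(ord))) return(run)
  K <- length(ord)
  perm_theta <- vector("list", K)
  for (new_i in seq_len(K)) {
    old_i <- ord[new_i]
    # rebuild row new_i's logits relative to its (new) self category
    old_row <- run$theta[[old_i]]                       # (K-1) x p
    eta_full <- matrix(0, K, ncol(old_row))
    eta_full[setdiff(seq_len(K), old_i), ] <- old_row
    eta_perm <- eta_full[ord, , drop = FALSE]
    eta_perm <- sweep(eta_perm, 2, eta_perm[new_i, ])   # re-reference to self
    perm_theta[[new_i]] <- eta_perm[setdiff(seq_len(K), new_i), , drop = FALSE]
  }
  run$log_means <- run$log_means[ord]
  run$means <- run$means[ord]
  run$log_sds <- run$log_sds[ord]
  run$init <- run$init[ord]
  run$theta <- perm_theta
  run$trans <- run$trans[ord, ord, , drop = FALSE]
  run$gamma <- run$gamma[, ord, drop = FALSE]
  run
}

#' Posterior state-probability profile over the 24-h day
#'
#' Runs forward-backward smoothing with the fitted model over the full
#' record and averages the per-minute posteriors by minute-of-day across
#' days, giving a 1440-point profile whose three state probabilities sum
#' to 1 everywhere. Missing minutes are marginalised (their emission term
#' is dropped), so gaps do not distort the profile.
#'
#' @param model a fitted `harmonic_hmm`.
#' @param activity optionally a new `phys_ts` to smooth; defaults to the
#'   training series.
#' @return an object of class `state_profile`: data.frame `minute`
#'   (0..1439), `p_rest`, `p_moderate`, `p_high`, `n` (days contributing).
#' @export
state_posteriors <- function(model, activity = NULL) {
  if (is.null(activity)) {
    x <- model$logx; minute <- model$activity_minute
    gamma <- model$gamma
  } else {
    g <- minute_grid(activity)
    x <- g$x; minute <- g$minute
    K <- length(model$log_means)
    ld <- matrix(0, length(x), K)
    obs <- !is.na(x)
    for (k in seq_len(K)) {
      ld[obs, k] <- stats::dnorm(x[obs], model$log_means[k],
                                 model$log_sds[k], log = TRUE)
    }
    gamma <- fb_pass(ld, model$init, as.numeric(model$trans), minute)$gamma
  }
  grid <- 0:1439
  f <- factor(minute, levels = grid)
  prof <- data.frame(
    minute = grid,
    p_rest = as.numeric(tapply(gamma[, 1], f, mean)),
    p_moderate = as.numeric(tapply(gamma[, 2], f, mean)),
    p_high = as.numeric(tapply(gamma[, 3], f, mean)),
    n = as.integer(table(f))
  )
  structure(prof, class = c("state_profile", "data.frame"))
}

#' Center-of-rest time: gravity center of the inactive-state profile
#'
#' The circular center of mass of minute-of-day, weighted by the posterior
#' probability of the inactive/rest state: the angle of the resultant
#' vector of the 1440 minute angles. Rest spans typically straddle
#' midnight, so a linear centroid would be wrong across the wrap; the
#' circular version handles it exactly.
#'
#' @param profile a `state_profile` (or data.frame with `minute`, `p_rest`).
#' @return a [clock_phase()]; `NA` if the inactive-state mass is zero.
#' @export
center_of_rest <- function(profile) {
  w <- profile$p_rest
  w[is.na(w)] <- 0
  # each minute bin is weighted at its midpoint, so a rectangular rest
  # probability on [00:00, 08:00) centers exactly at 04:00
  circular_mean_hours((profile$minute + 0.5) / 60, w)
}
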