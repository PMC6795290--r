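#' The published INTime coefficients
#'
#' The fixed-coefficient instance of the bathyphase predictor:
#' core temperature bathyphase = 1.33 x sex - 0.058 x chronotype score
#' + 0.472 x center-of-rest time - 0.145 x chest temperature bathyphase,
#' with sex coded 1 for male and 0 for female and all phases in decimal
#' hours. There is no intercept.
#'
#' @return an object of class `published_intime` with the immutable
#'   coefficient vector.
#' @export
published_intime <- function() {
  structure(
    list(coef = c(sex = 1.33, chronotype_score = -0.058,
                  center_of_rest = 0.472, chest_bathyphase = -0.145),
         intercept = 0),
    class = "published_intime"
  )
}

#' Pairwise covariate screen for phase predictors
#'
#' Spearman rank correlations among all continuous phase estimates and the
#' chronotype score, and two-sample t-tests of each phase by sex (and any
#' other binary covariate supplied). Two-tailed p-values; pairs with fewer
#' than 3 complete observations are reported as missing. Cells with
#' p < 0.1 are flagged as possible effects.
#'
#' @param phases data.frame of per-subject phase estimates (decimal hours;
#'   columns are screened pairwise). Must share `subject_id` with
#'   `subjects`.
#' @param subjects a [subject_record()] table.
#' @return list of data.frames: `spearman` (var1, var2, r, p, n, flag) and
#'   `t_tests` (group, variable, estimate, p, flag).
#' @export
correlation_screen <- function(phases, subjects) {
  df <- merge(phases, subjects, by = "subject_id")
  if (nrow(df) < 5) stop("need at least 5 complete rows")
  cont <- c(setdiff(names(phases), "subject_id"), "chronotype_score", "age", "bmi")
  cont <- intersect(cont, names(df))
  pairs <- utils::combn(cont, 2)
  sp <- apply(pairs, 2, function(pr) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) {
      return(data.frame(var1 = pr[1], var2 = pr[2], r = NA_real_,
                        p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(var1 = pr[1], var2 = pr[2], r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  })
  sp <- do.call(rbind, sp)
  sp$flag <- !is.na(sp$p) & sp$p < 0.1

  bins <- c("sex", if ("concurrent_treatment" %in% names(df)) "concurrent_treatment")
  tt <- do.call(rbind, lapply(bins, function(b) {
    do.call(rbind, lapply(setdiff(names(phases), "subject_id"), function(v) {
      g <- df[[b]]; y <- df[[v]]
      ok <- stats::complete.cases(g, y)
      if (length(unique(g[ok])) < 2 || min(table(g[ok])) < 2) {
        return(data.frame(group = b, variable = v, diff = NA_real_,
                          p = NA_real_, n = sum(ok)))
      }
      ht <- stats::t.test(y[ok] ~ g[ok])
      data.frame(group = b, variable = v,
                 diff = unname(diff(rev(ht$estimate))), p = ht$p.value,
                 n = sum(ok))
    }))
  }))
  tt$flag <- !is.na(tt$p) & tt$p < 0.1
  list(spearman = sp, t_tests = tt)
}

## corrected AIC for a fitted lm: AIC + 2k(k+1)/(n-k-1), k = edf incl. sigma
aicc <- function(fit) {
  n <- stats::nobs(fit)
  k <- attr(stats::logLik(fit), "df")
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the INTime model by bidirectional stepwise AICc selection
#'
#' Starting from the full model (outcome: core temperature bathyphase on
#' the unwrapped hour axis; candidates: sex, age, BMI, chronotype score,
#' DLMO, center-of-rest, chest acrophase and bathyphase), repeatedly takes
#' the single add-or-drop move that most improves the corrected Akaike
#' information criterion for small samples (AICc) until no move improves
#' it. Candidate moves are compared on the complete cases of the full
#' candidate set; the selected model is then refit on the complete cases
#' of the selected covariates only, so subjects missing e.g. DLMO are
#' retained whenever DLMO is not selected.
#'
#' @param phases data.frame with `subject_id`, the outcome column
#'   `core_bathyphase`, and candidate phase columns.
#' @param subjects a [subject_record()] table.
#' @param candidates character vector of candidate covariate names
#'   (columns of `phases` or `subjects`).
#' @param intercept include an intercept (default `TRUE`; the published
#'   equation is printed without one).
#' @return an object of class `intime_model`: the final `lm` fit, selected
#'   covariate names, coefficients, adjusted R^2, residuals, residual SD,
#'   selection trace (AICc after each accepted move), and the data used.
#' @export
fit_intime <- function(phases, subjects,
                       candidates = c("sex", "age", "bmi", "chronotype_score",
                                      "dlmo", "center_of_rest",
                                      "chest_acrophase", "chest_bathyphase"),
                       intercept = TRUE) {
  df <- merge(phases, subjects, by = "subject_id")
  candidates <- intersect(candidates, names(df))
  sel_df <- df[stats::complete.cases(df[c("core_bathyphase", candidates)]), ]
  n <- nrow(sel_df)
  if (n <= length(candidates) + 2) {
    stop("too few complete cases for AICc-based selection")
  }
  rhs <- function(vars) {
    paste(c(if (!intercept) "0", if (length(vars)) vars else "1"),
          collapse = " + ")
  }
  fit_on <- function(vars, data) {
    stats::lm(stats::as.formula(paste("core_bathyphase ~", rhs(vars))),
              data = data)
  }
  current <- candidates
  cur_fit <- fit_on(current, sel_df)
  trace <- data.frame(step = 0L, move = "<full model>", aicc = aicc(cur_fit),
                      stringsAsFactors = FALSE)
  repeat {
    moves <- list()
    for (v in current) {
      moves[[paste0("- ", v)]] <- setdiff(current, v)
    }
    for (v in setdiff(candidates, current)) {
      moves[[paste0("+ ", v)]] <- c(current, v)
    }
    if (!length(moves)) break
    scores <- vapply(moves, function(vars) aicc(fit_on(vars, sel_df)),
                     numeric(1))
    best <- which.min(scores)
    if (scores[best] >= trace$aicc[nrow(trace)] - 1e-10) break
    current <- moves[[best]]
    cur_fit <- fit_on(current, sel_df)
    trace <- rbind(trace, data.frame(step = nrow(trace), move = names(best),
                                     aicc = scores[best]))
  }
  # refit on all subjects complete for the selected covariates
  fin_df <- df[stats::complete.cases(df[c("core_bathyphase", current)]), ]
  fin <- fit_on(current, fin_df)
  out <- list(
    fit = fin, selected = current,
    coef = stats::coef(fin),
    adj_r2 = summary(fin)$adj.r.squared,
    residuals = stats::residuals(fin),
    sigma = summary(fin)$sigma,
    trace = trace, data = fin_df, intercept = intercept,
    n_selection = n, n_final = nrow(fin_df)
  )
  class(out) <- "intime_model"
  out
}

#' @export
print.intime_model <- function(x, ...) {
  cat("INTime bathyphase model (stepwise AICc)\n")
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  print(round(x$coef, 4))
  cat(sprintf("adjusted R^2 = %.3f, residual SD = %.3f h, n = %d\n",
              x$adj_r2, x$sigma, x$n_final))
  invisible(x)
}

#' Predict core temperature bathyphase
#'
#' Linear prediction in decimal hours. For a fitted `intime_model` a 90%
#' (or `level`) prediction band is returned (t quantile times the
#' predictive standard error for a new observation); the published
#' fixed-coefficient equation stores no residual variance and returns a
#' point prediction only.
#'
#' @param model an `intime_model` or [published_intime()].
#' @param covariates data.frame with the model's covariate columns.
#' @param level prediction-band level (default 0.90).
#' @return data.frame with `predicted` (decimal hours; also as
#'   [clock_phase()] in `predicted_phase`) and, for fitted models, `lo`
#'   and `hi` band bounds.
#' @export
predict_bathyphase <- function(model, covariates, level = 0.90) {
  if (inherits(model, "published_intime")) {
    need <- names(model$coef)
    miss <- setdiff(need, names(covariates))
    if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
    pred <- as.numeric(as.matrix(covariates[need]) %*% model$coef) +
      model$intercept
    return(data.frame(predicted = pred,
                      predicted_phase = unclass(clock_phase(pred))))
  }
  stopifnot(inherits(model, "intime_model"))
  miss <- setdiff(model$selected, names(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  pr <- stats::predict(model$fit, newdata = covariates,
                       interval = "prediction", level = level)
  data.frame(predicted = pr[, "fit"],
             predicted_phase = unclass(clock_phase(pr[, "fit"])),
             lo = pr[, "lwr"], hi = pr[, "upr"])
}

#' Accuracy of predicted versus measured bathyphases
#'
#' Signed errors (predicted minus measured) on the unwrapped hour axis,
#' summarised as the median, IQR, extremes, the fraction of subjects with
#' absolute error under 1 h (the clinical accuracy criterion), and -- when
#' prediction bands are supplied -- the fraction of measured values inside
#' their band.
#'
#' @param predicted numeric predicted bathyphases (decimal hours), or the
#'   data.frame from [predict_bathyphase()] (bands then used for coverage).
#' @param measured numeric measured bathyphases, same subjects, same order.
#' @return list: `errors_h`, `median_min`, `iqr_min`, `range_min`,
#'   `fraction_lt_1h`, `n`, and `band_coverage` when available.
#' @export
accuracy_summary <- function(predicted, measured) {
  bands <- NULL
  if (is.data.frame(predicted)) {
    if (all(c("lo", "hi") %in% names(predicted))) {
      bands <- predicted[c("lo", "hi")]
    }
    predicted <- predicted$predicted
  }
  if (length(predicted) != length(measured)) {
    stop("predicted and measured lengths differ")
  }
  err <- circular_diff(predicted, measured)
  out <- list(
    errors_h = err,
    median_min = stats::median(err) * 60,
    iqr_min = unname(stats::quantile(err, c(0.25, 0.75))) * 60,
    range_min = range(err) * 60,
    fraction_lt_1h = mean(abs(err) < 1),
    n = length(err)
  )
  if (!is.null(bands)) {
    inside <- circular_diff(measured, bands$lo) >= 0 &
      circular_diff(measured, bands$hi) <= 0
    out$band_coverage <- mean(inside)
  }
  out
}

#' Residual-bootstrap sample-size stability of the model fit
#'
#' Builds pseudo-datasets of arbitrary size n by resampling covariate rows
#' of the fitted model with replacement and adding resampled residuals to
#' the corresponding fitted values, refits the same covariates, and
#' collects the adjusted R^2 over `trials` Monte Carlo replicates. For
#' each confidence level the CI of adjusted R^2 is the central quantile
#' interval; the smallest n whose CI width falls below 10% of the
#' reference adjusted R^2 is reported per level.
#'
#' @param model an `intime_model`.
#' @param n_grid sample sizes to probe (each > model dimension + 2).
#' @param trials Monte Carlo replicates per n (default 1000).
#' @param ci_levels confidence levels (default c(0.90, 0.95)).
#' @param seed integer seed.
#' @param width_target CI width criterion as a fraction of the reference
#'   adjusted R^2 (default 0.10).
#' @return list: `table` (level, n, ci_lo, ci_hi, width), `required_n`
#'   (named by level; `NA` if no n in the grid qualifies), `reference_r2`.
#' @export
sample_size_stability <- function(model, n_grid, trials = 1000,
                                  ci_levels = c(0.90, 0.95), seed = 1L,
                                  width_target = 0.10) {
  stopifnot(inherits(model, "intime_model"))
  p <- length(stats::coef(model$fit))
  if (any(n_grid <= p + 2)) stop("n_grid values must exceed model dimension + 2")
  X <- stats::model.matrix(model$fit)
  yhat <- stats::fitted(model$fit)
  res <- stats::residuals(model$fit)
  n0 <- length(res)
  r2_of <- function(y, Xs) {
    fit <- stats::lm.fit(Xs, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    n <- length(y)
    1 - (rss / (n - p)) / (tss / (n - 1))
  }
  tab <- list()
  with_seed(seed, {
    for (n in sort(n_grid)) {
      r2 <- vapply(seq_len(trials), function(b) {
        rows <- sample.int(n0, n, replace = TRUE)
        y <- yhat[rows] + sample(res, n, replace = TRUE)
        r2_of(y, X[rows, , drop = FALSE])
      }, numeric(1))
      for (lv in ci_levels) {
        qs <- stats::quantile(r2, c((1 - lv) / 2, 1 - (1 - lv) / 2),
                              names = FALSE)
        tab[[length(tab) + 1]] <- data.frame(
          level = lv, n = n, ci_lo = qs[1], ci_hi = qs[2],
          width = diff(qs))
      }
    }
  })
  tab <- do.call(rbind, tab)
  ref <- model$adj_r2
  req <- vapply(ci_levels, function(lv) {
    sub <- tab[tab$level == lv & tab$width < width_target * ref, ]
    if (nrow(sub)) min(sub$n) else NA_real_
  }, numeric(1))
  list(table = tab, required_n = stats::setNames(req, ci_levels),
       reference_r2 = ref)
}
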