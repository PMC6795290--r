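test_that("the published equation reproduces its printed coefficients", {
  eq <- published_intime()
  unit <- function(var) {
    cov <- data.frame(sex = 0, chronotype_score = 0, center_of_rest = 0,
                      chest_bathyphase = 0)
    cov[[var]] <- 1
    predict_bathyphase(eq, cov)$predicted
  }
  expect_identical(unit("sex"), 1.33)
  expect_identical(unit("chronotype_score"), -0.058)
  expect_identical(unit("center_of_rest"), 0.472)
  expect_identical(unit("chest_bathyphase"), -0.145)
  zero <- data.frame(sex = 0, chronotype_score = 0, center_of_rest = 0,
                     chest_bathyphase = 0)
  expect_identical(predict_bathyphase(eq, zero)$predicted, 0)
  # linearity: +1 h of center-of-rest moves the prediction by +0.472 h
  a <- data.frame(sex = 1, chronotype_score = 55, center_of_rest = 27,
                  chest_bathyphase = 11)
  b <- a; b$center_of_rest <- b$center_of_rest + 1
  expect_equal(predict_bathyphase(eq, b)$predicted -
                 predict_bathyphase(eq, a)$predicted, 0.472,
               tolerance = 1e-12)
  expect_error(predict_bathyphase(eq, a[-1]), "sex")
})

test_that("the covariate screen recovers planted rank correlations", {
  n <- 200
  ranks <- sample(n)
  phases <- data.frame(subject_id = sprintf("S%03d", 1:n),
                       core_bathyphase = ranks,
                       center_of_rest = -ranks + rnorm(n, 0, 1e-9))
  subj <- subject_record(phases$subject_id, rep(0:1, n / 2),
                         rep(40, n), rep(24, n), sample(16:86, n, TRUE))
  sc <- correlation_screen(phases, subj)
  row <- sc$spearman[sc$spearman$var1 == "core_bathyphase" &
                       sc$spearman$var2 == "center_of_rest", ]
  expect_equal(row$r, -1)

  tr <- generate_cohort(200, seed = 31)
  sc2 <- correlation_screen(truth_phase_table(tr), truth_subjects(tr))
  row2 <- sc2$spearman[sc2$spearman$var1 == "center_of_rest" &
                         sc2$spearman$var2 == "chronotype_score", ]
  expect_lt(abs(row2$r - (-0.7)), 0.15)
  expect_true(row2$flag)
  expect_error(correlation_screen(phases[1:3, ], subj), "at least 5")
})

test_that("stepwise AICc improves at every accepted step and recovers truth", {
  tr <- generate_cohort(200, seed = 37)
  m <- fit_intime(truth_phase_table(tr), truth_subjects(tr))
  expect_true(all(diff(m$trace$aicc) < 0))
  expect_true(all(c("sex", "chronotype_score", "center_of_rest",
                    "chest_bathyphase") %in% m$selected))
  expect_lte(m$adj_r2, 1)
  # refit coefficients near the generating slopes
  truth_coef <- c(sex = 1.33, chronotype_score = -0.058,
                  center_of_rest = 0.472, chest_bathyphase = -0.145)
  se <- coef(summary(m$fit))[names(truth_coef), "Std. Error"]
  expect_true(all(abs(m$coef[names(truth_coef)] - truth_coef) < 2.5 * se))
})

test_that("pure-noise candidates are almost entirely pruned away", {
  # AICc admits a spurious covariate at the chi-square(1) > ~2 rate of
  # about 16% per candidate, so the expected selected size on 6 pure-noise
  # candidates is ~0.9 with the empty model the single most likely outcome
  set.seed(43)
  hits <- replicate(20, {
    n <- 60
    phases <- data.frame(subject_id = sprintf("S%03d", 1:n),
                         core_bathyphase = rnorm(n, 27.5, 1.2),
                         center_of_rest = rnorm(n, 27, 1),
                         chest_bathyphase = rnorm(n, 11, 2))
    subj <- subject_record(phases$subject_id, rep(0:1, n / 2),
                           round(runif(n, 21, 78)), rnorm(n, 24, 3),
                           sample(16:86, n, TRUE))
    m <- fit_intime(phases, subj,
                    candidates = c("sex", "age", "bmi", "chronotype_score",
                                   "center_of_rest", "chest_bathyphase"))
    length(m$selected)
  })
  expect_gt(mean(hits <= 1), 0.7)
  expect_lt(mean(hits), 1.5)
})

test_that("prediction bands attain roughly nominal within-sample coverage", {
  tr <- generate_cohort(200, seed = 41)
  m <- fit_intime(truth_phase_table(tr), truth_subjects(tr))
  pred <- predict_bathyphase(m, m$data, level = 0.90)
  acc <- accuracy_summary(pred, m$data$core_bathyphase)
  expect_lt(abs(acc$band_coverage - 0.90), 0.05)
})

test_that("accuracy summaries count signed errors correctly", {
  same <- accuracy_summary(c(27, 28, 26.5), c(27, 28, 26.5))
  expect_equal(same$median_min, 0)
  expect_equal(same$fraction_lt_1h, 1)
  errs_min <- c(-30, 10, 50, 70)
  acc <- accuracy_summary(27 + errs_min / 60, rep(27, 4))
  expect_equal(acc$fraction_lt_1h, 0.75)
  expect_equal(sort(acc$errors_h * 60), sort(errs_min), tolerance = 1e-9)
  expect_error(accuracy_summary(1:3, 1:4), "lengths differ")
})

test_that("sample-size stability is deterministic and degenerate without noise", {
  tr <- generate_cohort(40, seed = 47, sim_config(eq_noise_sd = 0))
  # lm warns about the essentially perfect fit; that is the point here
  m0 <- suppressWarnings(
    fit_intime(truth_phase_table(tr), truth_subjects(tr),
               candidates = c("sex", "chronotype_score", "center_of_rest",
                              "chest_bathyphase")))
  st0 <- sample_size_stability(m0, n_grid = c(50, 100), trials = 50, seed = 3)
  expect_true(all(st0$table$width < 1e-6))

  tr2 <- generate_cohort(40, seed = 47)
  m2 <- fit_intime(truth_phase_table(tr2), truth_subjects(tr2))
  a <- sample_size_stability(m2, n_grid = c(50, 150), trials = 60, seed = 9)
  b <- sample_size_stability(m2, n_grid = c(50, 150), trials = 60, seed = 9)
  expect_identical(a$table, b$table)
  expect_error(sample_size_stability(m2, n_grid = c(4, 100), trials = 10),
               "model dimension")
})
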