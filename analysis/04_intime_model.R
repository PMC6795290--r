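#!/usr/bin/env Rscript
# Screen candidate predictors, fit the INTime model of core temperature
# bathyphase by bidirectional stepwise AICc, and summarise within-sample
# prediction accuracy and 90% prediction-band coverage. Writes
# results/intime/.

library(circaphase)

out <- "results/intime"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
truth <- read.csv("results/cohort/truth.csv")
phases <- read.csv("results/phases.csv")
subjects <- subject_record(truth$subject_id, truth$sex, truth$age,
                           truth$bmi, truth$chronotype_score)

screen <- correlation_screen(
  phases[c("subject_id", "dlmo", "core_acrophase", "core_bathyphase",
           "chest_acrophase", "chest_bathyphase", "center_of_rest")],
  subjects)
write.csv(screen$spearman, file.path(out, "screen_spearman.csv"),
          row.names = FALSE)
write.csv(screen$t_tests, file.path(out, "screen_t_tests.csv"),
          row.names = FALSE)
flagged <- screen$spearman[screen$spearman$flag, ]
cat("correlations flagged at p < 0.1:\n")
print(flagged[order(flagged$p), c("var1", "var2", "r", "p")], digits = 2)

model <- fit_intime(phases, subjects)
print(model)
pred <- predict_bathyphase(model, model$data)
acc <- accuracy_summary(pred, model$data$core_bathyphase)
cat(sprintf("accuracy: median error %.0f min (IQR %.0f to %.0f), |err| < 1 h for %.1f%%\n",
            acc$median_min, acc$iqr_min[1], acc$iqr_min[2],
            100 * acc$fraction_lt_1h))
cat(sprintf("90%% prediction bands cover %.1f%% of measured bathyphases\n",
            100 * acc$band_coverage))

jsonlite::write_json(
  list(selected = model$selected, coef = as.list(round(model$coef, 4)),
       adj_r2 = model$adj_r2, sigma_h = model$sigma, n = model$n_final,
       trace = model$trace,
       accuracy = acc[c("median_min", "iqr_min", "range_min",
                        "fraction_lt_1h", "band_coverage")]),
  file.path(out, "intime_model.json"), auto_unbox = TRUE, digits = NA)

# the published fixed-coefficient instance, for comparison on this cohort
eq <- published_intime()
pub <- predict_bathyphase(eq, model$data)
r_pub <- cor(pub$predicted, model$data$core_bathyphase)
cat(sprintf("published-coefficient predictor (no intercept): r = %.2f with measured bathyphase\n",
            r_pub))
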