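#' Subject covariate records
#'
#' Per-subject covariates used by the bathyphase predictor: sex (coded 1 for
#' male, 0 for female), age in years, BMI in kg/m^2, the
#' morningness-eveningness questionnaire (MEQ) score (16--86) and its
#' category, and whether the subject was on any concurrent treatment.
#'
#' @param subject_id character vector.
#' @param sex integer vector, 1 = male, 0 = female.
#' @param age numeric, years.
#' @param bmi numeric, kg/m^2.
#' @param chronotype_score integer MEQ score in 16--86.
#' @param concurrent_treatment logical, default `FALSE`.
#' @return a data.frame with class `subject_record`, one row per subject,
#'   including the derived `chronotype_category`.
#' @export
subject_record <- function(subject_id, sex, age, bmi, chronotype_score,
                           concurrent_treatment = FALSE) {
  if (!all(sex %in% c(0L, 1L))) stop("sex must be coded 0 (female) or 1 (male)")
  structure(
    data.frame(
      subject_id = as.character(subject_id),
      sex = as.integer(sex),
      age = as.numeric(age),
      bmi = as.numeric(bmi),
      chronotype_score = as.integer(chronotype_score),
      chronotype_category = categorize_chronotype(chronotype_score),
      concurrent_treatment = rep_len(as.logical(concurrent_treatment),
                                     length(subject_id)),
      stringsAsFactors = FALSE
    ),
    class = c("subject_record", "data.frame")
  )
}

#' Categorize an MEQ chronotype score
#'
#' Standard Horne-Ostberg bands: 16--41 evening, 42--58 intermediate,
#' 59--86 morning. The bands partition the full score range with no gaps.
#'
#' @param score integer vector in 16--86.
#' @return character vector in `c("evening", "intermediate", "morning")`.
#' @examples
#' categorize_chronotype(c(20, 50, 70))
#' @export
categorize_chronotype <- function(score) {
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 16L | score > 86L))) {
    stop("chronotype score out of range [16, 86]")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score <= 41L, "evening",
                ifelse(score <= 58L, "intermediate", "morning")))
}

#' Read subject covariates from CSV
#' @param path CSV with columns subject_id, sex, age, bmi, chronotype_score
#'   and optionally concurrent_treatment.
#' @return a [subject_record()] table.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "bmi", "chronotype_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("format error: missing column(s) %s",
                                 paste(miss, collapse = ", ")))
  ct <- if ("concurrent_treatment" %in% names(df)) df$concurrent_treatment else FALSE
  subject_record(df$subject_id, df$sex, df$age, df$bmi, df$chronotype_score, ct)
}
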