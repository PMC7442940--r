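AGE_BANDS <- data.frame(
  band = c("35-44", "45-54", "55-64", "65-75"),
  min = c(35, 45, 55, 65),
  max = c(44, 54, 64, 75),
  stringsAsFactors = FALSE
)

age_band_of <- function(age) {
  idx <- findInterval(age, c(AGE_BANDS$min, Inf))
  out <- AGE_BANDS$band[idx]
  out[age < AGE_BANDS$min[1] | age > AGE_BANDS$max[nrow(AGE_BANDS)]] <-
    NA_character_
  out
}

#' Risk-factor summary for one user sample
#'
#' The descriptive summary reported for each engagement-funnel sample
#' (anonymous users, users who requested a report, survey respondents):
#' gender counts and percentages, mean and SD of age, age-band counts
#' (35-44, 45-54, 55-64, 65-75), and counts/percentages for smoking,
#' family history, diabetes, blood-pressure medication, and knowing
#' one's blood pressure and cholesterol levels. Percentages are on the
#' sample size, rounded to 2 dp; the SD is the sample (n-1) form.
#'
#' @param records A data frame with columns `sex`, `age`, `smoker`,
#'   `family_history`, `diabetes`, `on_bp_medication`, `sbp_known`,
#'   `cholesterol_known`.
#' @param sample_label A label for the sample (e.g. `"report"`).
#' @return A data frame of class `cohort_summary` with columns
#'   `measure`, `count`, `percent`, `value` (the latter holding mean /
#'   SD age), plus attributes `n` and `sample`.
#' @export
summarize_risk_factors <- function(records, sample_label = "sample") {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n == 0) stop("empty cohort", call. = FALSE)
  required <- c("sex", "age", "smoker", "family_history", "diabetes",
                "on_bp_medication", "sbp_known", "cholesterol_known")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pct <- function(k) round(100 * k / n, 2)
  row <- function(measure, count = NA_integer_, percent = NA_real_,
                  value = NA_real_) {
    data.frame(measure = measure, count = count, percent = percent,
               value = value, stringsAsFactors = FALSE)
  }
  bands <- table(factor(age_band_of(records$age),
                        levels = AGE_BANDS$band))
  out <- rbind(
    row("n", count = n),
    row("female", sum(records$sex == "female"),
        pct(sum(records$sex == "female"))),
    row("male", sum(records$sex == "male"),
        pct(sum(records$sex == "male"))),
    row("age_mean", value = round(mean(records$age), 2)),
    row("age_sd", value = round(stats::sd(records$age), 2)),
    do.call(rbind, lapply(AGE_BANDS$band, function(b) {
      row(paste0("age_", b), as.integer(bands[[b]]), pct(bands[[b]]))
    })),
    row("smoker", sum(records$smoker), pct(sum(records$smoker))),
    row("family_history", sum(records$family_history),
        pct(sum(records$family_history))),
    row("diabetes", sum(records$diabetes), pct(sum(records$diabetes))),
    row("on_bp_medication", sum(records$on_bp_medication),
        pct(sum(records$on_bp_medication))),
    row("sbp_known", sum(records$sbp_known),
        pct(sum(records$sbp_known))),
    row("cholesterol_known", sum(records$cholesterol_known),
        pct(sum(records$cholesterol_known)))
  )
  attr(out, "n") <- n
  attr(out, "sample") <- sample_label
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Distribution of heart-age results across a cohort
#'
#' Summarizes computed heart-age results: the mean and sample SD of
#' the gap between heart age and chronological age, the percentage in
#' each category (younger / equal / older), and category counts
#' stratified by sex and age band.
#'
#' @param results A data frame with columns `heart_age_raw`,
#'   `category`, `sex`, `age`.
#' @return A list of class `heart_age_distribution`: `n`, `gap_mean`,
#'   `gap_sd`, `category_counts`, `category_percent`, and `strata` (a
#'   data frame of counts by sex, age band and category).
#' @export
heart_age_distribution <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) stop("empty cohort", call. = FALSE)
  required <- c("heart_age_raw", "category", "sex", "age")
  missing <- setdiff(required, names(results))
  if (length(missing)) {
    stop("results are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gap <- results$heart_age_raw - results$age
  cats <- factor(results$category, levels = c("younger", "equal", "older"))
  counts <- table(cats)
  strata <- as.data.frame(table(
    sex = results$sex,
    age_band = factor(age_band_of(results$age), levels = AGE_BANDS$band),
    category = cats
  ), responseName = "count", stringsAsFactors = FALSE)
  structure(list(
    n = nrow(results),
    gap_mean = mean(gap),
    gap_sd = if (nrow(results) > 1) stats::sd(gap) else NA_real_,
    category_counts = c(counts),
    category_percent = round(100 * c(counts) / nrow(results), 2),
    strata = strata
  ), class = "heart_age_distribution")
}

#' @export
print.heart_age_distribution <- function(x, ...) {
  cat(sprintf(
    "<heart_age_distribution> n = %d; heart age %.2f (SD %.2f) years %s current age\n",
    x$n, abs(x$gap_mean), x$gap_sd,
    if (x$gap_mean >= 0) "older than" else "younger than"))
  cat(sprintf("  older %.2f%%, equal %.2f%%, younger %.2f%%\n",
              x$category_percent[["older"]],
              x$category_percent[["equal"]],
              x$category_percent[["younger"]]))
  invisible(x)
}
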