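#' Heart-age reporting bounds and solver settings
#'
#' Heart age is reported as a whole number of years, censored at the
#' display bounds: results below the minimum show as `"<35"` and
#' results at or above the maximum as `">=85"` (the raw continuous
#' value is always retained). The solver inverts the ideal-risk curve
#' by monotone bisection on a wide age bracket so that arbitrary
#' coefficient sets — including ones with age interactions — are
#' supported.
#'
#' @param display_min,display_max Censoring bounds in years for the
#'   displayed heart age.
#' @param bracket Two ages bounding the bisection search.
#' @param tol Bisection convergence tolerance in years.
#' @return A list of settings for [heart_age()].
#' @export
heart_age_bounds <- function(display_min = 35, display_max = 85,
                             bracket = c(20, 120), tol = 1e-6) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], tol > 0)
  list(display_min = display_min, display_max = display_max,
       bracket = bracket, tol = tol)
}

# Ideal-risk-factor referent at a given age: non-smoker, non-diabetic,
# untreated ideal SBP, ideal lipids, no family history. When the
# coefficient set uses BMI, height is set to 100 cm so weight equals
# the configured ideal BMI numerically.
ideal_profile_at <- function(age, sex, coeffs) {
  ideal <- coeffs$ideal
  risk_profile(
    age = age, sex = sex, smoker = FALSE, diabetes = FALSE,
    height = 100, weight = ideal$bmi %||% NA_real_,
    sbp = ideal$sbp, on_bp_medication = FALSE,
    total_cholesterol = ideal$total_cholesterol,
    hdl_cholesterol = ideal$hdl_cholesterol,
    family_history = FALSE
  )
}

#' Ten-year risk of the ideal referent at a given age
#'
#' The risk of a person of the given sex and age with ideal risk-factor
#' levels (non-smoker, non-diabetic, systolic blood pressure 120 mmHg
#' untreated, total cholesterol 4 mmol/L under the default
#' configuration). Heart age is the age at which this curve equals the
#' user's own risk; with a positive age beta it is strictly increasing,
#' so the inversion is well defined.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param coeffs A `coefficient_set`.
#' @return A `risk_value`.
#' @export
ideal_risk_at_age <- function(age, sex, coeffs) {
  ten_year_risk(ideal_profile_at(age, sex, coeffs), coeffs)
}

# round half away from zero (display convention; round() halves to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare heart age with chronological age
#'
#' Both ages are rounded to whole years (half away from zero) before
#' comparison, so a heart age of 54.4 is "equal" for a 54-year-old; a
#' tie is "equal".
#'
#' @param heart_age_raw Continuous heart age in years.
#' @param chronological_age Age in years.
#' @return `"younger"`, `"equal"`, or `"older"`.
#' @export
categorize <- function(heart_age_raw, chronological_age) {
  h <- round_half_away(heart_age_raw)
  a <- round_half_away(chronological_age)
  ifelse(h < a, "younger", ifelse(h > a, "older", "equal"))
}

#' Convert absolute risk to heart age
#'
#' Solves for the age at which the ideal-risk-factor referent of the
#' user's sex has the same 10-year absolute risk as the user, by
#' monotone bisection over the configured age bracket. A risk below
#' (above) the ideal risk at the bracket ends is clamped to the nearer
#' bracket bound and flagged, never raised as an error. The displayed
#' heart age is the whole-year rounding, censored at the display bounds
#' (`"<35"` / `">=85"`), and categorized against the chronological age.
#'
#' @param profile A validated, fully imputed [risk_profile()].
#' @param coeffs A `coefficient_set`.
#' @param bounds See [heart_age_bounds()].
#' @return An object of class `heart_age_result`: `risk` (a
#'   `risk_value`), `heart_age_raw`, `heart_age_display`, `category`,
#'   `bracket_clamped` (`"none"`, `"low"` or `"high"`), `display_censored`,
#'   and `advisories`.
#' @examples
#' coeffs <- default_coefficients("lipid")
#' p <- impute_unknowns(risk_profile(55, "male", smoker = TRUE))
#' heart_age(p, coeffs)
#' @export
heart_age <- function(profile, coeffs, bounds = heart_age_bounds()) {
  stopifnot(inherits(profile, "risk_profile"))
  rv <- ten_year_risk(profile, coeffs)
  target <- rv$risk
  lo <- bounds$bracket[1]
  hi <- bounds$bracket[2]
  f <- function(a) ideal_risk_at_age(a, profile$sex, coeffs)$risk - target
  flo <- f(lo)
  fhi <- f(hi)
  clamped <- "none"
  if (flo >= 0) {
    raw <- lo
    clamped <- "low"
  } else if (fhi <= 0) {
    raw <- hi
    clamped <- "high"
  } else {
    # iterate well past the guaranteed age tolerance so the returned
    # age also matches the target risk to high precision on the ideal
    # curve (the extra iterations are a handful of cheap evaluations)
    iter <- 0L
    while (hi - lo > bounds$tol * 1e-6 && iter < 80L) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
    raw <- (lo + hi) / 2
  }
  rounded <- round_half_away(raw)
  if (rounded < bounds$display_min) {
    display <- paste0("<", fmt_num(bounds$display_min))
    censored <- TRUE
  } else if (rounded >= bounds$display_max) {
    display <- paste0("≥", fmt_num(bounds$display_max))
    censored <- TRUE
  } else {
    display <- fmt_num(rounded)
    censored <- FALSE
  }
  structure(list(
    risk = rv,
    heart_age_raw = raw,
    heart_age_display = display,
    category = categorize(raw, profile$age),
    bracket_clamped = clamped,
    display_censored = censored,
    advisories = validation_message(character(0), character(0),
                                    character(0))
  ), class = "heart_age_result")
}

#' @export
print.heart_age_result <- function(x, ...) {
  cat(sprintf("<heart_age_result> heart age %s (%s; raw %.2f y), 10-year risk %.2f%%\n",
              x$heart_age_display, x$category, x$heart_age_raw,
              100 * x$risk$risk))
  if (nrow(x$advisories)) {
    cat("  advisories:\n")
    for (i in seq_len(nrow(x$advisories))) {
      cat("   - [", x$advisories$severity[i], "] ",
          x$advisories$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Validate, impute and compute a heart age in one call
#'
#' The full calculator flow for one user: inputs are validated against
#' the plausibility rules; any `range_error` blocks the calculation
#' (the result carries the messages and no heart age, mirroring the
#' web form's re-entry prompt). Otherwise unknowns are imputed from the
#' population-average table and the heart age computed; high-risk
#' advisories and eligibility warnings are attached to the result
#' without blocking it.
#'
#' @inheritParams heart_age
#' @param table An imputation table, see [read_imputation_table()].
#' @param rules Validation rules, see [default_validation_rules()].
#' @return A `heart_age_result`; when blocked, `heart_age_raw` is `NA`
#'   and `category` is `NA`. The result additionally carries
#'   `sbp_imputed` and `cholesterol_imputed` flags.
#' @export
calculate_heart_age <- function(profile, coeffs = default_coefficients(),
                                table = read_imputation_table(),
                                rules = default_validation_rules(),
                                bounds = heart_age_bounds()) {
  msgs <- validate_inputs(profile, rules)
  if (any(msgs$severity == "range_error")) {
    res <- structure(list(
      risk = NULL, heart_age_raw = NA_real_,
      heart_age_display = NA_character_, category = NA_character_,
      bracket_clamped = "none", display_censored = FALSE,
      advisories = msgs
    ), class = "heart_age_result")
    res$sbp_imputed <- !profile$sbp_known
    res$cholesterol_imputed <- !profile$cholesterol_known
    return(res)
  }
  imputed <- impute_unknowns(profile, table)
  res <- heart_age(imputed, coeffs, bounds)
  res$advisories <- msgs
  res$sbp_imputed <- !profile$sbp_known
  res$cholesterol_imputed <- !profile$cholesterol_known
  res
}

#' Render a heart-age report
#'
#' Assembles the emailed report's computed content as plain
#' text/Markdown: the heart age and its category sentence, the
#' estimated 10-year risk, a per-risk-factor summary, a note whenever a
#' population average stood in for an unknown value, the heart health
#' check recommendation for users in the target age group, and any
#' advisories raised at validation.
#'
#' @param result A `heart_age_result`.
#' @param profile The [risk_profile()] the result was computed from.
#' @param target_age Two ages bounding the heart-health-check target
#'   group.
#' @return A single character string (lines separated by newlines).
#' @export
render_report <- function(result, profile, target_age = c(45, 75)) {
  stopifnot(inherits(result, "heart_age_result"),
            inherits(profile, "risk_profile"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("# Your heart age report")
  if (is.na(result$heart_age_raw)) {
    add("Your heart age could not be calculated until all values are ",
        "within the accepted ranges.")
  } else {
    add("Your heart age is ", result$heart_age_display, ".")
    add(switch(result$category,
      older = sprintf(
        "Your heart age is older than your current age of %s years.",
        fmt_num(profile$age)),
      younger = sprintf(
        "Your heart age is younger than your current age of %s years.",
        fmt_num(profile$age)),
      equal = sprintf(
        "Your heart age is the same as your current age of %s years.",
        fmt_num(profile$age))
    ))
    add(sprintf(
      "Your estimated risk of a heart attack or stroke in the next 10 years is %.1f%%.",
      100 * result$risk$risk))
  }
  add("")
  add("## Your risk factors")
  add("- Smoking: ", if (profile$smoker) "yes" else "no")
  add("- Diabetes: ", if (profile$diabetes) "yes" else "no")
  add("- Family history of premature heart disease: ",
      if (profile$family_history) "yes" else "no")
  add("- Blood pressure medication: ",
      if (profile$on_bp_medication) "yes" else "no")
  add("- Systolic blood pressure: ",
      if (isTRUE(result$sbp_imputed)) "not known (population average used)"
      else paste0(fmt_num(profile$sbp), " mm Hg"))
  add("- Total cholesterol: ",
      if (isTRUE(result$cholesterol_imputed))
        "not known (population average used)"
      else paste0(fmt_num(profile$total_cholesterol), " mmol/L"))
  if (isTRUE(result$sbp_imputed) || isTRUE(result$cholesterol_imputed)) {
    add("")
    add("Because you did not know some of your values, a population ",
        "average for your age and sex was used in the calculation. ",
        "Your result will be more accurate with your own measurements.")
  }
  if (!is.na(profile$age) && profile$age >= target_age[1] &&
      profile$age <= target_age[2]) {
    add("")
    add("You are in the target age group for a heart health check: ",
        "see your doctor for a heart health check to get a full ",
        "absolute cardiovascular risk assessment.")
  }
  if (identical(result$category, "older")) {
    add("")
    add("Your result is older than your current age, which means at ",
        "least one of your risk factors is above the ideal level. We ",
        "recommend you see your doctor to discuss your heart health.")
  }
  if (nrow(result$advisories)) {
    add("")
    add("## Important messages")
    for (i in seq_len(nrow(result$advisories))) {
      add("- ", result$advisories$message[i])
    }
  }
  paste(lines, collapse = "\n")
}
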