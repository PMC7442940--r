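#' Default input-validation rules
#'
#' Plausibility ranges and high-risk advisory thresholds for user
#' inputs, mirroring an Australian guideline-based deployment:
#' cholesterol must lie in 2-10.5 mmol/L, and a plausible value above
#' 7.5 mmol/L triggers a see-your-doctor advisory without blocking the
#' calculation. The systolic-blood-pressure plausibility range (70-250
#' mmHg) and high-risk threshold (180 mmHg) are package defaults chosen
#' to match guideline practice; both are configuration, not fixed
#' clinical constants. The eligibility window is the calculator's
#' target age range of 35-75 years.
#'
#' @return A nested list of rule thresholds, editable before passing to
#'   [validate_inputs()].
#' @export
default_validation_rules <- function() {
  list(
    total_cholesterol = list(min = 2, max = 10.5, high = 7.5),
    sbp = list(min = 70, max = 250, high = 180),
    age = list(min = 35, max = 75)
  )
}

validation_message <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Validate raw calculator inputs
#'
#' Checks a profile against plausibility and advisory rules before any
#' imputation. Three severities are produced: `range_error` (an
#' implausible value; blocks calculation and prompts re-entry with the
#' accepted range), `high_risk_advisory` (a plausible but
#' guideline-high value; the heart age is still calculated, and a
#' pop-up urges a doctor visit), and `eligibility_warning` (age outside
#' the calculator's 35-75 target range). Unknown values produce no
#' messages — they are handled by imputation.
#'
#' @param profile A [risk_profile()] with raw user inputs (unknowns
#'   permitted).
#' @param rules Rule thresholds, see [default_validation_rules()].
#' @return A data frame with columns `severity`, `field`, `message`
#'   (zero rows when everything is in range).
#' @examples
#' p <- risk_profile(50, "female", total_cholesterol = 1.5)
#' validate_inputs(p)$message  # range prompt
#' @export
validate_inputs <- function(profile, rules = default_validation_rules()) {
  stopifnot(inherits(profile, "risk_profile"))
  msgs <- list()
  tc <- profile$total_cholesterol
  r <- rules$total_cholesterol
  if (profile$cholesterol_known && !is.na(tc)) {
    if (tc < r$min || tc > r$max) {
      msgs[[length(msgs) + 1L]] <- validation_message(
        "range_error", "total_cholesterol",
        sprintf("Please enter a number between %s and %s",
                fmt_num(r$min), fmt_num(r$max)))
    } else if (tc > r$high) {
      msgs[[length(msgs) + 1L]] <- validation_message(
        "high_risk_advisory", "total_cholesterol",
        sprintf(paste0("Total cholesterol above %s mmol/L puts you at ",
                       "high risk of having a heart attack or stroke. ",
                       "Please see your doctor as soon as possible ",
                       "about your cholesterol."), fmt_num(r$high)))
    }
  }
  sb <- profile$sbp
  r <- rules$sbp
  if (profile$sbp_known && !is.na(sb)) {
    if (sb < r$min || sb > r$max) {
      msgs[[length(msgs) + 1L]] <- validation_message(
        "range_error", "sbp",
        sprintf("Please enter a number between %s and %s",
                fmt_num(r$min), fmt_num(r$max)))
    } else if (sb > r$high) {
      msgs[[length(msgs) + 1L]] <- validation_message(
        "high_risk_advisory", "sbp",
        sprintf(paste0("Blood pressure above %s mm Hg puts you at high ",
                       "risk of having a heart attack or stroke. Please ",
                       "see your doctor as soon as possible about your ",
                       "blood pressure."), fmt_num(r$high)))
    }
  }
  r <- rules$age
  if (!is.na(profile$age) && (profile$age < r$min || profile$age > r$max)) {
    msgs[[length(msgs) + 1L]] <- validation_message(
      "eligibility_warning", "age",
      sprintf("This calculator is intended for people aged %s to %s years.",
              fmt_num(r$min), fmt_num(r$max)))
  }
  if (length(msgs) == 0) {
    return(validation_message(character(0), character(0), character(0)))
  }
  do.call(rbind, msgs)
}
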