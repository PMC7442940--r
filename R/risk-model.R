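#' Construct a cardiovascular risk profile
#'
#' One person's risk-factor vector in natural clinical units, as
#' collected by the web calculator: age, sex, family history of
#' premature heart disease, smoking status, height, weight, diabetes
#' status, systolic blood pressure, total cholesterol, and
#' blood-pressure-medication status. Blood pressure and cholesterol may
#' be unknown (`NA`); the known/unknown flags drive imputation and are
#' preserved for reporting. HDL cholesterol is never user-entered — it
#' is filled from the population-average table by sex and age band (see
#' [impute_unknowns()]).
#'
#' @param age Age in whole years (the calculator targets 35-75).
#' @param sex `"female"` or `"male"`.
#' @param smoker,diabetes,family_history,on_bp_medication Logical flags.
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @param sbp Systolic blood pressure, mmHg, or `NA` if unknown.
#' @param total_cholesterol Total cholesterol, mmol/L, or `NA` if unknown.
#' @param hdl_cholesterol HDL cholesterol, mmol/L; normally left `NA`
#'   and supplied by imputation.
#' @param sbp_known,cholesterol_known Known/unknown flags; default to
#'   whether the value was supplied.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(age, sex, smoker = FALSE, diabetes = FALSE,
                         height = NA_real_, weight = NA_real_,
                         sbp = NA_real_, on_bp_medication = FALSE,
                         total_cholesterol = NA_real_,
                         hdl_cholesterol = NA_real_,
                         family_history = FALSE,
                         sbp_known = !is.na(sbp),
                         cholesterol_known = !is.na(total_cholesterol)) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.na(height) && height <= 0) {
    stop("height must be positive", call. = FALSE)
  }
  if (!is.na(weight) && weight <= 0) {
    stop("weight must be positive", call. = FALSE)
  }
  structure(list(
    age = as.numeric(age), sex = sex,
    smoker = isTRUE(smoker), diabetes = isTRUE(diabetes),
    height = as.numeric(height), weight = as.numeric(weight),
    sbp = as.numeric(sbp), on_bp_medication = isTRUE(on_bp_medication),
    total_cholesterol = as.numeric(total_cholesterol),
    hdl_cholesterol = as.numeric(hdl_cholesterol),
    family_history = isTRUE(family_history),
    sbp_known = isTRUE(sbp_known),
    cholesterol_known = isTRUE(cholesterol_known)
  ), class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("<risk_profile> %s, %g y; smoker=%s diabetes=%s famhx=%s\n",
              x$sex, x$age, x$smoker, x$diabetes, x$family_history))
  cat(sprintf("  SBP %s mmHg (%s%s), TC %s mmol/L (%s), HDL %s mmol/L\n",
              ifelse(is.na(x$sbp), "?", format(x$sbp)),
              if (x$sbp_known) "known" else "unknown",
              if (x$on_bp_medication) ", treated" else "",
              ifelse(is.na(x$total_cholesterol), "?",
                     format(x$total_cholesterol)),
              if (x$cholesterol_known) "known" else "unknown",
              ifelse(is.na(x$hdl_cholesterol), "?",
                     format(x$hdl_cholesterol))))
  invisible(x)
}

#' Body-mass index from height and weight
#'
#' @param height Height in cm, > 0.
#' @param weight Weight in kg, > 0.
#' @return BMI in kg/m^2.
#' @examples
#' bmi_from_height_weight(180, 81)  # 25
#' @export
bmi_from_height_weight <- function(height, weight) {
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive finite numbers",
         call. = FALSE)
  }
  weight / (height / 100)^2
}

# mg/dL per mmol/L for cholesterol
MG_PER_MMOL_CHOL <- 38.67

#' Transformed covariate vector for a risk equation
#'
#' Maps a fully imputed profile onto the covariates named by the
#' coefficient set: lipids are converted from mmol/L to the set's
#' declared unit (38.67 mg/dL per mmol/L) before any transform, BMI is
#' derived from height and weight when the set names it, and each
#' covariate's declared transform (identity or natural log) is applied.
#'
#' @param profile A [risk_profile()] with no remaining unknowns among
#'   the covariates the coefficient set requires.
#' @param coeffs A `coefficient_set`.
#' @return Named numeric vector on the transformed scale.
#' @export
to_model_units <- function(profile, coeffs) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(coeffs, "coefficient_set"))
  terms <- coeffs$sexes[[profile$sex]]$terms
  lipid_scale <- if (coeffs$lipid_units == "mg/dL") MG_PER_MMOL_CHOL else 1
  needed <- unique(terms$covariate)
  vals <- vapply(needed, function(cv) {
    raw <- switch(cv,
      age = profile$age,
      sbp = profile$sbp,
      total_cholesterol = profile$total_cholesterol * lipid_scale,
      hdl_cholesterol = profile$hdl_cholesterol * lipid_scale,
      smoker = as.numeric(profile$smoker),
      diabetes = as.numeric(profile$diabetes),
      bmi = bmi_from_height_weight(profile$height, profile$weight),
      stop("coefficient set requires unsupported covariate: ", cv,
           call. = FALSE)
    )
    if (is.na(raw)) {
      stop("covariate required by the coefficient set is missing from ",
           "the profile: ", cv, " (impute before computing risk)",
           call. = FALSE)
    }
    tf <- terms$transform[match(cv, terms$covariate)]
    if (tf == "log") log(raw) else raw
  }, numeric(1))
  names(vals) <- needed
  vals
}

#' Linear predictor of the proportional-hazards risk equation
#'
#' The beta-weighted sum over transformed covariates. When the
#' coefficient set carries treated and untreated systolic-blood-pressure
#' betas, the one matching the profile's medication status is used. A
#' configured family-history hazard multiplier enters additively as its
#' natural log when family history is present.
#'
#' @inheritParams to_model_units
#' @return The linear predictor (dimensionless).
#' @export
linear_predictor <- function(profile, coeffs) {
  x <- to_model_units(profile, coeffs)
  terms <- coeffs$sexes[[profile$sex]]$terms
  use <- is.na(terms$when_treated) |
    terms$when_treated == profile$on_bp_medication
  terms <- terms[use, , drop = FALSE]
  lp <- sum(terms$beta * x[terms$covariate])
  if (profile$family_history) {
    lp <- lp + log(coeffs$family_history_hazard_multiplier)
  }
  lp
}

#' Ten-year absolute cardiovascular risk
#'
#' The probability of a first cardiovascular event (heart attack or
#' stroke) within 10 years, from the sex-specific survival-function
#' form \deqn{risk = 1 - S_0^{\exp(LP - \bar{LP})}} where \eqn{S_0} is
#' the baseline 10-year survival and \eqn{\bar{LP}} the derivation
#' cohort's mean linear predictor.
#'
#' @inheritParams to_model_units
#' @return A list of class `risk_value` with elements `risk` (in (0,1))
#'   and `linear_predictor`.
#' @examples
#' coeffs <- default_coefficients("lipid")
#' p <- risk_profile(61, "female", smoker = TRUE, sbp = 124,
#'                   total_cholesterol = 180 / 38.67,
#'                   hdl_cholesterol = 47 / 38.67)
#' ten_year_risk(p, coeffs)$risk  # ~0.105
#' @export
ten_year_risk <- function(profile, coeffs) {
  lp <- linear_predictor(profile, coeffs)
  blk <- coeffs$sexes[[profile$sex]]
  risk <- 1 - blk$s0^exp(lp - blk$mean_linear_predictor)
  structure(list(risk = risk, linear_predictor = lp),
            class = "risk_value")
}

#' @export
print.risk_value <- function(x, ...) {
  cat(sprintf("<risk_value> 10-year CVD risk %.2f%% (LP %.4f)\n",
              100 * x$risk, x$linear_predictor))
  invisible(x)
}
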