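#' Load a risk-equation coefficient set from a YAML configuration file
#'
#' A coefficient set describes a sex-specific Framingham-style
#' proportional-hazards risk equation: per-covariate regression terms
#' (each with a transform and beta), the 10-year baseline survival
#' \eqn{S_0}, and the mean linear predictor of the derivation cohort.
#' All numeric content is configuration data; the package never
#' hard-codes betas, so a deployed calculator's recalibrated weightings
#' can be dropped in without code changes.
#'
#' The YAML schema, per sex (`female:`, `male:`):
#' \describe{
#'   \item{`s0`}{baseline 10-year survival, in (0, 1).}
#'   \item{`mean_linear_predictor`}{optional; the derivation-cohort mean
#'     of the linear predictor. If absent, every term must carry a
#'     `mean:` entry (reference value on the transformed scale) and the
#'     mean linear predictor is the beta-weighted sum of those means,
#'     using the untreated-SBP beta.}
#'   \item{`terms`}{a list of `{covariate, transform, beta}` entries.
#'     `transform` is `identity` or `log` (natural log). Systolic blood
#'     pressure may appear twice, distinguished by `when_treated:
#'     true/false`, selecting the beta by blood-pressure-medication
#'     status.}
#' }
#' Top-level keys: `lipid_units` (`mmol/L` or `mg/dL`; user inputs are
#' always mmol/L and are converted on the way in when the equation was
#' published in mg/dL), `family_history_hazard_multiplier` (default 1:
#' family history is collected but has no effect unless configured), and
#' `ideal` (the referent risk-factor levels used for heart-age
#' inversion).
#'
#' @param path Path to a YAML coefficient file.
#' @return An object of class `coefficient_set`.
#' @seealso [default_coefficients()] for the configurations shipped with
#'   the package, [ten_year_risk()] for the risk equation itself.
#' @export
load_coefficients <- function(path) {
  if (!file.exists(path)) {
    stop("coefficient file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  as_coefficient_set(raw, source = path)
}

#' Coefficient configurations shipped with the package
#'
#' Two ready-to-use transcriptions of the general cardiovascular disease
#' Framingham risk equations (sex-specific Cox models, 10-year horizon):
#' the lipid-based equation (`"lipid"`, the default; covariates log age,
#' log total and HDL cholesterol in mg/dL, log systolic blood pressure
#' with separate treated/untreated betas, smoking, diabetes) and the
#' office-based variant (`"bmi"`) that replaces the lipid terms with log
#' body-mass index so a heart age can be computed from height and weight
#' alone. Both are replaceable: national deployments recalibrate
#' weightings for local guidelines, and such modified sets load through
#' [load_coefficients()] unchanged.
#'
#' @param model `"lipid"` or `"bmi"`.
#' @return A `coefficient_set`.
#' @export
default_coefficients <- function(model = c("lipid", "bmi")) {
  model <- match.arg(model)
  file <- switch(model,
    lipid = "framingham-general-lipid.yaml",
    bmi   = "framingham-general-bmi.yaml"
  )
  load_coefficients(system.file("extdata", file, package = "heartage",
                                mustWork = TRUE))
}

as_coefficient_set <- function(raw, source = "<inline>") {
  for (sx in c("female", "male")) {
    if (is.null(raw[[sx]])) {
      stop("coefficient set must define both sexes; missing: ", sx,
           call. = FALSE)
    }
  }
  cs <- list(
    model = raw$model %||% "unnamed",
    horizon_years = raw$horizon_years %||% 10,
    lipid_units = raw$lipid_units %||% "mmol/L",
    family_history_hazard_multiplier =
      raw$family_history_hazard_multiplier %||% 1.0,
    ideal = raw$ideal %||% list(sbp = 120, total_cholesterol = 4.0,
                                hdl_cholesterol = 1.3),
    sexes = list(),
    source = source
  )
  if (!cs$lipid_units %in% c("mmol/L", "mg/dL")) {
    stop("lipid_units must be 'mmol/L' or 'mg/dL'", call. = FALSE)
  }
  if (cs$family_history_hazard_multiplier <= 0) {
    stop("family_history_hazard_multiplier must be positive", call. = FALSE)
  }
  for (sx in c("female", "male")) {
    blk <- raw[[sx]]
    terms <- do.call(rbind, lapply(blk$terms, function(tm) {
      data.frame(
        covariate = tm$covariate,
        transform = tm$transform %||% "identity",
        beta = as.numeric(tm$beta),
        when_treated = if (is.null(tm$when_treated)) NA else
          isTRUE(tm$when_treated),
        mean = if (is.null(tm$mean)) NA_real_ else as.numeric(tm$mean),
        stringsAsFactors = FALSE
      )
    }))
    s0 <- as.numeric(blk$s0)
    if (!is.finite(s0) || s0 <= 0 || s0 >= 1) {
      stop("baseline survival s0 must lie strictly in (0, 1) for ", sx,
           call. = FALSE)
    }
    bad_tf <- setdiff(terms$transform, c("identity", "log"))
    if (length(bad_tf)) {
      stop("unknown transform(s): ", paste(bad_tf, collapse = ", "),
           call. = FALSE)
    }
    age_beta <- terms$beta[terms$covariate == "age"]
    if (length(age_beta) == 0 || any(age_beta <= 0)) {
      stop("coefficient set must include an age term with positive beta (",
           sx, ")", call. = FALSE)
    }
    mlp <- blk$mean_linear_predictor
    if (is.null(mlp)) {
      if (anyNA(terms$mean)) {
        stop("for ", sx, ": either mean_linear_predictor or a mean for ",
             "every term is required", call. = FALSE)
      }
      keep <- is.na(terms$when_treated) | !terms$when_treated
      mlp <- sum(terms$beta[keep] * terms$mean[keep])
    }
    cs$sexes[[sx]] <- list(s0 = s0, mean_linear_predictor = as.numeric(mlp),
                           terms = terms)
  }
  class(cs) <- "coefficient_set"
  cs
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> ", x$model, " (", x$horizon_years,
      "-year horizon, lipids in ", x$lipid_units, ")\n", sep = "")
  for (sx in names(x$sexes)) {
    blk <- x$sexes[[sx]]
    cat(sprintf("  %s: S0 = %.5f, mean LP = %.4f, %d terms\n",
                sx, blk$s0, blk$mean_linear_predictor, nrow(blk$terms)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariates needed by a sex block (unique names)
covariates_required <- function(coeffs, sex) {
  unique(coeffs$sexes[[sex]]$terms$covariate)
}
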