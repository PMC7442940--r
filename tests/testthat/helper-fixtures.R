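# shared fixture builders; everything is generated in code

# a coefficient set built from an inline spec (same schema as the YAML)
make_coeffs <- function(female_terms, male_terms = female_terms,
                        s0_female = 0.95, s0_male = 0.89,
                        mlp_female = NULL, mlp_male = NULL,
                        lipid_units = "mmol/L", fh_multiplier = 1.0,
                        ideal = list(sbp = 120, total_cholesterol = 4.0,
                                     hdl_cholesterol = 1.3)) {
  heartage:::as_coefficient_set(list(
    model = "test", lipid_units = lipid_units,
    family_history_hazard_multiplier = fh_multiplier,
    ideal = ideal,
    female = list(s0 = s0_female, mean_linear_predictor = mlp_female,
                  terms = female_terms),
    male = list(s0 = s0_male, mean_linear_predictor = mlp_male,
                terms = male_terms)
  ))
}

term <- function(covariate, beta, transform = "identity",
                 when_treated = NULL, mean = NULL) {
  tm <- list(covariate = covariate, transform = transform, beta = beta)
  if (!is.null(when_treated)) tm$when_treated <- when_treated
  if (!is.null(mean)) tm$mean <- mean
  tm
}

# small lipid-style set with simple betas, mmol/L units, mean LP 0
simple_coeffs <- function(beta_age = 1.5, beta_smoker = 0.5,
                          beta_sbp = 1.0, beta_tc = 0.4,
                          s0 = 0.95, mlp = 10, fh_multiplier = 1.0) {
  terms <- list(
    term("age", beta_age, "log"),
    term("sbp", beta_sbp, "log", when_treated = FALSE),
    term("sbp", beta_sbp + 0.1, "log", when_treated = TRUE),
    term("total_cholesterol", beta_tc, "log"),
    term("smoker", beta_smoker)
  )
  make_coeffs(terms, s0_female = s0, s0_male = s0,
              mlp_female = mlp, mlp_male = mlp,
              fh_multiplier = fh_multiplier)
}

# a random plausible profile with everything known
random_profile <- function(sex = sample(c("female", "male"), 1)) {
  risk_profile(
    age = sample(35:75, 1), sex = sex,
    smoker = runif(1) < 0.2, diabetes = runif(1) < 0.1,
    height = runif(1, 150, 195), weight = runif(1, 50, 110),
    sbp = runif(1, 95, 180), on_bp_medication = runif(1) < 0.25,
    total_cholesterol = runif(1, 3, 8.5),
    hdl_cholesterol = runif(1, 0.8, 2.2),
    family_history = runif(1) < 0.4
  )
}

# independent term-by-term linear predictor: reads the term table and
# sums beta * transformed value by hand, no package risk code involved
oracle_lp <- function(profile, coeffs) {
  terms <- coeffs$sexes[[profile$sex]]$terms
  scale <- if (coeffs$lipid_units == "mg/dL") 38.67 else 1
  lp <- 0
  for (i in seq_len(nrow(terms))) {
    wt <- terms$when_treated[i]
    if (!is.na(wt) && wt != profile$on_bp_medication) next
    v <- switch(terms$covariate[i],
      age = profile$age, sbp = profile$sbp,
      total_cholesterol = profile$total_cholesterol * scale,
      hdl_cholesterol = profile$hdl_cholesterol * scale,
      smoker = as.numeric(profile$smoker),
      diabetes = as.numeric(profile$diabetes),
      bmi = profile$weight / (profile$height / 100)^2
    )
    if (terms$transform[i] == "log") v <- log(v)
    lp <- lp + terms$beta[i] * v
  }
  if (profile$family_history) {
    lp <- lp + log(coeffs$family_history_hazard_multiplier)
  }
  lp
}

oracle_risk <- function(profile, coeffs) {
  blk <- coeffs$sexes[[profile$sex]]
  1 - blk$s0^exp(oracle_lp(profile, coeffs) - blk$mean_linear_predictor)
}

# closed-form heart age when age enters only as beta * log(age):
# solve LP_ideal(a*) = LP(profile) by rearranging the log-age term
closed_form_heart_age <- function(profile, coeffs) {
  terms <- coeffs$sexes[[profile$sex]]$terms
  beta_age <- terms$beta[terms$covariate == "age"]
  ideal <- heartage:::ideal_profile_at(profile$age, profile$sex, coeffs)
  dlp <- linear_predictor(profile, coeffs) -
    linear_predictor(ideal, coeffs)
  profile$age * exp(dlp / beta_age)
}
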