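coeffs <- default_coefficients("lipid")

test_that("implausible and high-risk inputs produce the calculator's messages", {
  p <- risk_profile(50, "female", total_cholesterol = 1.5)
  msgs <- validate_inputs(p)
  expect_equal(msgs$severity, "range_error")
  expect_identical(msgs$message,
                   "Please enter a number between 2 and 10.5")

  p <- risk_profile(50, "female", total_cholesterol = 8.0)
  msgs <- validate_inputs(p)
  expect_equal(msgs$severity, "high_risk_advisory")
  expect_match(msgs$message, "above 7.5 mmol/L", fixed = TRUE)
  expect_identical(
    msgs$message,
    paste0("Total cholesterol above 7.5 mmol/L puts you at high risk ",
           "of having a heart attack or stroke. Please see your ",
           "doctor as soon as possible about your cholesterol."))

  # everything in range: no messages
  p <- risk_profile(50, "female", total_cholesterol = 5.0, sbp = 120)
  expect_equal(nrow(validate_inputs(p)), 0)

  # SBP rules are config: defaults flag implausible and high values
  expect_equal(validate_inputs(
    risk_profile(50, "male", sbp = 60))$severity, "range_error")
  expect_equal(validate_inputs(
    risk_profile(50, "male", sbp = 190))$severity,
    "high_risk_advisory")

  # age outside the 35-75 window warns but nothing blocks
  expect_equal(validate_inputs(
    risk_profile(80, "male"))$severity, "eligibility_warning")
})

test_that("advisories do not block the calculation but range errors do", {
  res <- calculate_heart_age(
    risk_profile(55, "male", total_cholesterol = 8.0, sbp = 130))
  expect_false(is.na(res$heart_age_raw))
  expect_true("high_risk_advisory" %in% res$advisories$severity)

  res <- calculate_heart_age(
    risk_profile(55, "male", total_cholesterol = 1.5))
  expect_true(is.na(res$heart_age_raw))
  expect_true("range_error" %in% res$advisories$severity)
})

test_that("unknown values are imputed from the sex and age band averages", {
  tab <- read_imputation_table()
  # fully known profile: values untouched, HDL filled from the table
  p <- risk_profile(52, "female", sbp = 117, total_cholesterol = 4.9)
  q <- impute_unknowns(p, tab)
  expect_equal(q$sbp, 117)
  expect_equal(q$total_cholesterol, 4.9)
  expect_false(is.na(q$hdl_cholesterol))
  expect_true(q$sbp_known && q$cholesterol_known)  # flags preserved

  # unknown cholesterol, female 52: the (female, 50-54) band value
  band <- tab[tab$sex == "female" & tab$age_min == 50, ]
  p <- risk_profile(52, "female", sbp = 117)
  expect_equal(impute_unknowns(p, tab)$total_cholesterol,
               band$total_cholesterol)

  # both unknown: both equal their band means (direct table oracle)
  p <- risk_profile(52, "female")
  q <- impute_unknowns(p, tab)
  expect_equal(q$sbp, band$sbp)
  expect_equal(q$total_cholesterol, band$total_cholesterol)
  expect_equal(q$hdl_cholesterol, band$hdl_cholesterol)
  expect_false(q$sbp_known)                        # flags preserved

  # age outside every band is a configuration error
  expect_error(impute_unknowns(risk_profile(30, "male"), tab),
               "no imputation band")
})

test_that("the ideal profile maps back to its own age (inversion identity)", {
  for (sx in c("female", "male")) {
    for (a in c(35, 47, 60, 75)) {
      ip <- heartage:::ideal_profile_at(a, sx, coeffs)
      expect_lt(abs(heart_age(ip, coeffs)$heart_age_raw - a), 0.01)
    }
  }
  # and under the office-based configuration too
  coeffs_bmi <- default_coefficients("bmi")
  ip <- heartage:::ideal_profile_at(50, "male", coeffs_bmi)
  expect_lt(abs(heart_age(ip, coeffs_bmi)$heart_age_raw - 50), 0.01)
})

test_that("ideal risk increases with age and equals 1 - S0 under zero betas", {
  expect_gt(ideal_risk_at_age(60, "male", coeffs)$risk,
            ideal_risk_at_age(40, "male", coeffs)$risk)
  zero <- simple_coeffs(s0 = 0.92, mlp = 0)
  for (sx in c("female", "male")) zero$sexes[[sx]]$terms$beta <- 0
  for (a in c(35, 55, 75)) {
    expect_equal(ideal_risk_at_age(a, "female", zero)$risk, 1 - 0.92)
  }
})

test_that("uncensored heart age matches the profile's risk on the ideal curve", {
  set.seed(3)
  for (i in 1:20) {
    p <- random_profile()
    res <- heart_age(p, coeffs)
    if (res$bracket_clamped == "none") {
      expect_equal(
        ideal_risk_at_age(res$heart_age_raw, p$sex, coeffs)$risk,
        res$risk$risk, tolerance = 1e-9)
    }
  }
})

test_that("bisection agrees with the closed-form log-age rearrangement", {
  set.seed(5)
  bounds <- heart_age_bounds()
  for (i in 1:100) {
    p <- random_profile()
    res <- heart_age(p, coeffs, bounds)
    a_star <- closed_form_heart_age(p, coeffs)
    a_star <- min(max(a_star, bounds$bracket[1]), bounds$bracket[2])
    expect_lt(abs(res$heart_age_raw - a_star), 1e-6)
  }
})

test_that("worsening a positively weighted risk factor never lowers heart age", {
  p <- heartage:::ideal_profile_at(50, "male", coeffs)
  base <- heart_age(p, coeffs)
  expect_equal(base$category, "equal")
  smoker <- p
  smoker$smoker <- TRUE
  res <- heart_age(smoker, coeffs)
  expect_gt(res$heart_age_raw, 50)
  expect_equal(res$category, "older")
  hi_bp <- p
  hi_bp$sbp <- 140
  expect_gt(heart_age(hi_bp, coeffs)$heart_age_raw,
            base$heart_age_raw)
})

test_that("heart age category compares whole-year roundings, half away from zero", {
  expect_equal(categorize(54.4, 54), "equal")
  expect_equal(categorize(59.6, 54), "older")
  expect_equal(categorize(50.2, 54), "younger")
  expect_equal(categorize(54.5, 54), "older")   # half rounds away
  expect_equal(categorize(54.0, 54), "equal")   # tie is equal
})

test_that("display is censored at the bounds while the raw value is kept", {
  # extreme risk: old male smoker with diabetes and high BP/cholesterol
  p <- risk_profile(75, "male", smoker = TRUE, diabetes = TRUE,
                    sbp = 200, total_cholesterol = 9,
                    hdl_cholesterol = 0.8, on_bp_medication = TRUE)
  res <- heart_age(p, coeffs)
  expect_equal(res$heart_age_display, "≥85")
  expect_true(res$display_censored)
  expect_gte(res$heart_age_raw, 85)

  # sub-ideal young profile: better-than-ideal risk factors
  p <- risk_profile(35, "female", sbp = 100, total_cholesterol = 2.5,
                    hdl_cholesterol = 2.2)
  res <- heart_age(p, coeffs)
  expect_equal(res$heart_age_display, "<35")
  expect_true(res$display_censored)
  expect_lt(res$heart_age_raw, 35)
  expect_true(is.finite(res$heart_age_raw))
})

test_that("risk outside the bracket's range clamps instead of erroring", {
  # flat ideal curve (tiny age beta) so a strong smoking term pushes the
  # risk outside the range the ideal referent can reach in [20, 120]
  flat <- function(beta_smoker) {
    make_coeffs(list(term("age", 0.1, "log"),
                     term("smoker", beta_smoker)),
                s0_female = 0.95, s0_male = 0.95,
                mlp_female = 0, mlp_male = 0)
  }
  smoker <- risk_profile(50, "male", smoker = TRUE)
  expect_silent(hi <- heart_age(smoker, flat(3)))
  expect_equal(hi$bracket_clamped, "high")
  expect_equal(hi$heart_age_raw, 120)
  expect_silent(lo <- heart_age(smoker, flat(-3)))
  expect_equal(lo$bracket_clamped, "low")
  expect_equal(lo$heart_age_raw, 20)
})

test_that("the report states the result, imputation, and recommendations", {
  p <- risk_profile(50, "male", smoker = TRUE)  # BP/chol unknown
  res <- calculate_heart_age(p)
  txt <- render_report(res, p)
  expect_match(txt, "Your heart age is")
  expect_match(txt, "population average")
  expect_match(txt, "heart health check")       # in target age group
  expect_match(txt, "see your doctor")          # older result

  ip <- heartage:::ideal_profile_at(50, "female", coeffs)
  res_eq <- heart_age(ip, coeffs)
  res_eq$sbp_imputed <- FALSE
  res_eq$cholesterol_imputed <- FALSE
  txt_eq <- render_report(res_eq, ip)
  expect_match(txt_eq, "same as your current age")
})
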