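test_that("BMI is weight over squared height in metres", {
  expect_equal(bmi_from_height_weight(100, 25), 25)
  expect_equal(bmi_from_height_weight(180, 81), 25)
  expect_equal(round(bmi_from_height_weight(165, 70), 2), 25.71)
  expect_error(bmi_from_height_weight(0, 70), "positive")
  expect_error(bmi_from_height_weight(165, -1), "positive")
})

test_that("transforms and lipid unit conversion are applied as declared", {
  coeffs <- make_coeffs(list(
    term("age", 1, "log"),
    term("sbp", 1, "identity"),
    term("total_cholesterol", 1, "log")
  ), mlp_female = 0, mlp_male = 0, lipid_units = "mg/dL")
  p <- risk_profile(age = 1, sex = "female", sbp = 120,
                    total_cholesterol = 4)
  x <- to_model_units(p, coeffs)
  expect_equal(x[["sbp"]], 120)          # identity passes through
  expect_equal(x[["age"]], 0)            # ln 1
  expect_equal(x[["total_cholesterol"]], log(4 * 38.67))  # ln(154.68)

  # mmol/L set leaves lipids unconverted
  coeffs_mmol <- make_coeffs(list(
    term("age", 1, "log"),
    term("total_cholesterol", 1, "log")
  ), mlp_female = 0, mlp_male = 0, lipid_units = "mmol/L")
  expect_equal(to_model_units(p, coeffs_mmol)[["total_cholesterol"]],
               log(4))
})

test_that("missing required covariate raises a configuration error", {
  coeffs <- make_coeffs(list(term("age", 1, "log"),
                             term("sbp", 1, "log")),
                        mlp_female = 0, mlp_male = 0)
  p <- risk_profile(age = 50, sex = "male")  # sbp unknown, not imputed
  expect_error(to_model_units(p, coeffs), "sbp")
})

test_that("linear predictor matches a term-by-term oracle", {
  set.seed(42)
  for (i in 1:50) {
    coeffs <- simple_coeffs(
      beta_age = runif(1, 0.5, 3), beta_smoker = runif(1, -1, 1),
      beta_sbp = runif(1, 0.5, 3), beta_tc = runif(1, -1, 1),
      s0 = runif(1, 0.7, 0.99), mlp = runif(1, -5, 25),
      fh_multiplier = runif(1, 0.5, 2)
    )
    p <- random_profile()
    expect_equal(linear_predictor(p, coeffs), oracle_lp(p, coeffs),
                 tolerance = 1e-12)
    expect_equal(ten_year_risk(p, coeffs)$risk, oracle_risk(p, coeffs),
                 tolerance = 1e-12)
  }
})

test_that("treated and untreated blood-pressure betas are selected by medication status", {
  coeffs <- simple_coeffs(beta_sbp = 1)
  p_untreated <- risk_profile(50, "male", sbp = 140,
                              total_cholesterol = 5)
  p_treated <- p_untreated
  p_treated$on_bp_medication <- TRUE
  lp_u <- linear_predictor(p_untreated, coeffs)
  lp_t <- linear_predictor(p_treated, coeffs)
  expect_equal(lp_t - lp_u, 0.1 * log(140), tolerance = 1e-10)
})

test_that("family history enters as the log of the configured hazard multiplier", {
  coeffs <- simple_coeffs(fh_multiplier = 1.4)
  p <- risk_profile(50, "female", sbp = 130, total_cholesterol = 5)
  p_fh <- p
  p_fh$family_history <- TRUE
  expect_equal(linear_predictor(p_fh, coeffs) -
                 linear_predictor(p, coeffs), log(1.4))
  # default multiplier 1: no effect
  coeffs1 <- simple_coeffs()
  expect_equal(linear_predictor(p_fh, coeffs1),
               linear_predictor(p, coeffs1))
})

test_that("a profile at the per-covariate means has risk 1 - S0", {
  p <- risk_profile(50, "female", smoker = TRUE, sbp = 130,
                    total_cholesterol = 5)
  # build a set whose means are exactly this profile's transformed values
  terms <- list(
    term("age", 1.5, "log", mean = log(50)),
    term("sbp", 1.0, "log", when_treated = FALSE, mean = log(130)),
    term("sbp", 1.1, "log", when_treated = TRUE, mean = log(130)),
    term("total_cholesterol", 0.4, "log", mean = log(5)),
    term("smoker", 0.5, mean = 1)
  )
  coeffs <- make_coeffs(terms, s0_female = 0.93)
  expect_equal(ten_year_risk(p, coeffs)$risk, 1 - 0.93,
               tolerance = 1e-12)
})

test_that("zero betas give risk 1 - S0 for every profile", {
  coeffs <- simple_coeffs(s0 = 0.9, mlp = 0)
  for (sx in c("female", "male")) {
    coeffs$sexes[[sx]]$terms$beta <- 0
  }
  set.seed(7)
  for (i in 1:20) {
    p <- random_profile()
    expect_equal(ten_year_risk(p, coeffs)$risk, 1 - 0.9,
                 tolerance = 1e-12)
  }
})

test_that("risk lies in (0,1) and increases in positively weighted factors", {
  coeffs <- default_coefficients("lipid")
  set.seed(11)
  for (i in 1:30) {
    p <- random_profile()
    r <- ten_year_risk(p, coeffs)$risk
    expect_gt(r, 0)
    expect_lt(r, 1)
    bump <- function(field, delta) {
      q <- p
      q[[field]] <- q[[field]] + delta
      ten_year_risk(q, coeffs)$risk
    }
    expect_gt(bump("age", 1), r)
    expect_gt(bump("sbp", 5), r)
    expect_gt(bump("total_cholesterol", 0.5), r)
    if (!p$smoker) {
      q <- p
      q$smoker <- TRUE
      expect_gt(ten_year_risk(q, coeffs)$risk, r)
    }
    if (!p$diabetes) {
      q <- p
      q$diabetes <- TRUE
      expect_gt(ten_year_risk(q, coeffs)$risk, r)
    }
  }
})

test_that("default configuration reproduces an independent spreadsheet-style computation", {
  # independent route: read the YAML directly and sum the terms by hand
  path <- system.file("extdata", "framingham-general-lipid.yaml",
                      package = "heartage")
  raw <- yaml::read_yaml(path)
  hand_risk <- function(blk, vals, treated) {
    lp <- 0
    for (tm in blk$terms) {
      if (!is.null(tm$when_treated) && tm$when_treated != treated) next
      v <- vals[[tm$covariate]]
      if (identical(tm$transform, "log")) v <- log(v)
      lp <- lp + tm$beta * v
    }
    1 - blk$s0^exp(lp - blk$mean_linear_predictor)
  }
  coeffs <- default_coefficients("lipid")

  # worked female persona, values entered in mmol/L
  p <- risk_profile(61, "female", smoker = TRUE, sbp = 124,
                    total_cholesterol = 180 / 38.67,
                    hdl_cholesterol = 47 / 38.67)
  expected <- hand_risk(raw$female, list(
    age = 61, total_cholesterol = 180, hdl_cholesterol = 47,
    sbp = 124, smoker = 1, diabetes = 0), treated = FALSE)
  expect_equal(ten_year_risk(p, coeffs)$risk, expected,
               tolerance = 1e-9)

  # male smoker with diabetes and population-average BP/cholesterol
  imp <- read_imputation_table()
  p2 <- impute_unknowns(
    risk_profile(54, "male", smoker = TRUE, diabetes = TRUE),
    imp)
  band <- imp[imp$sex == "male" & imp$age_min <= 54 & imp$age_max >= 54, ]
  expected2 <- hand_risk(raw$male, list(
    age = 54, total_cholesterol = band$total_cholesterol * 38.67,
    hdl_cholesterol = band$hdl_cholesterol * 38.67,
    sbp = band$sbp, smoker = 1, diabetes = 1), treated = FALSE)
  expect_equal(ten_year_risk(p2, coeffs)$risk, expected2,
               tolerance = 1e-9)
})

test_that("coefficient configuration is validated on load", {
  expect_error(make_coeffs(list(term("age", 1, "log")),
                           s0_female = 1.2, mlp_female = 0,
                           mlp_male = 0), "s0")
  expect_error(make_coeffs(list(term("age", -1, "log")),
                           mlp_female = 0, mlp_male = 0),
               "positive beta")
  expect_error(make_coeffs(list(term("age", 1, "sqrt")),
                           mlp_female = 0, mlp_male = 0), "transform")
  # neither mean LP nor per-term means
  expect_error(make_coeffs(list(term("age", 1, "log"))), "mean")
})
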