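#' Configuration for the synthetic user-cohort generator
#'
#' Defines the marginal structure of a simulated national web-calculator
#' population and its engagement funnel (anonymous users, a self-selected
#' subset who sign up for an emailed report, and a further subset who
#' answer a follow-up survey). The defaults reproduce the published
#' anonymous-sample marginals and funnel of the Australian deployment:
#' 361,044 anonymous users of whom 30,279 requested a report and 1303
#' completed the survey; 61.29% female; age-band weights 40.00 / 24.63 /
#' 23.08 / 12.29% over 35-44 / 45-54 / 55-64 / 65-75; smoker 9.83%,
#' family history 34.26%, diabetes 5.71%, blood-pressure medication
#' 17.85%, blood pressure known 49.38%, cholesterol known 16.35%. The
#' engagement stages are Bernoulli selections whose probability is
#' logistic in standardized age and the two risk-factor-knowledge
#' flags (the published funnel skews older and more risk-aware), with
#' the intercept solved so the mean selection probability equals the
#' stage rate. Risk-factor values are truncated normals per sex with
#' clinically plausible moments; joint correlations are not modelled
#' (unreported), so factors are independent given the margins.
#'
#' @param n Number of anonymous users to generate.
#' @param p_female Proportion female.
#' @param age_band_weights Named weights over the four age bands.
#' @param rates Named list of marginal probabilities: `smoker`,
#'   `family_history`, `diabetes`, `on_bp_medication`, `sbp_known`,
#'   `cholesterol_known`.
#' @param values Truncated-normal settings (mean, sd, range) for `sbp`
#'   (mmHg), `total_cholesterol` (mmol/L), `height` (cm) and `bmi`
#'   (kg/m^2), per sex.
#' @param p_signup,p_survey Funnel stage probabilities.
#' @param engagement Logistic coefficients (on standardized age and the
#'   knowledge flags) for covariate-dependent engagement; all zero
#'   gives simple Bernoulli thinning.
#' @param seed Single integer seed; all stages draw from independent
#'   substreams derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n = 361044,
    p_female = 0.6129,
    age_band_weights = c("35-44" = 0.4000, "45-54" = 0.2463,
                         "55-64" = 0.2308, "65-75" = 0.1229),
    rates = list(smoker = 0.0983, family_history = 0.3426,
                 diabetes = 0.0571, on_bp_medication = 0.1785,
                 sbp_known = 0.4938, cholesterol_known = 0.1635),
    values = list(
      sbp = list(female = c(mean = 125, sd = 16),
                 male = c(mean = 130, sd = 15), range = c(70, 250)),
      total_cholesterol = list(female = c(mean = 5.6, sd = 1.0),
                               male = c(mean = 5.5, sd = 1.0),
                               range = c(2, 10.5)),
      height = list(female = c(mean = 162, sd = 7),
                    male = c(mean = 176, sd = 7), range = c(120, 220)),
      bmi = list(female = c(mean = 27, sd = 5.5),
                 male = c(mean = 27.5, sd = 4.5), range = c(16, 50))
    ),
    p_signup = 30279 / 361044,
    p_survey = 1303 / 30279,
    engagement = c(age = 0.8, sbp_known = 0.3, cholesterol_known = 0.3),
    seed = 1L) {
  probs <- c(p_female, unlist(rates), p_signup, p_survey)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1) stop("n must be positive", call. = FALSE)
  w <- age_band_weights
  if (any(w < 0) || sum(w) <= 0) {
    stop("age band weights must be nonnegative with positive sum",
         call. = FALSE)
  }
  structure(list(
    n = as.integer(n), p_female = p_female,
    age_band_weights = w / sum(w), rates = rates, values = values,
    p_signup = p_signup, p_survey = p_survey, engagement = engagement,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# evaluate fun() with the RNG positioned at substream `stream` of
# `seed` (L'Ecuyer-CMRG); global RNG state is restored afterwards
with_substream <- function(seed, stream, fun) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv,
                      inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = .GlobalEnv)
  for (i in seq_len(stream)) s <- parallel::nextRNGSubStream(s)
  assign(".Random.seed", s, envir = .GlobalEnv)
  fun()
}

# truncated normal via inverse-CDF of the truncated distribution
rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic anonymous user population
#'
#' Draws `config$n` user records with the configured marginal
#' structure: sex, an integer age uniform within a weighted age band,
#' Bernoulli risk-factor flags, truncated-normal heights and weights
#' (weight derived from a truncated-normal BMI), and systolic blood
#' pressure / total cholesterol values that are present only when the
#' corresponding knowledge flag is true (unknown values are `NA`, as in
#' the calculator's input). Fully reproducible for a given seed.
#'
#' @param config A [cohort_config()].
#' @return A data frame, one row per user, with a `user_id` column.
#' @export
generate_users <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  with_substream(config$seed, 1L, function() {
    sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
    band <- sample(AGE_BANDS$band, n, replace = TRUE,
                   prob = config$age_band_weights[AGE_BANDS$band])
    bi <- match(band, AGE_BANDS$band)
    age <- AGE_BANDS$min[bi] +
      floor(stats::runif(n) * (AGE_BANDS$max[bi] - AGE_BANDS$min[bi] + 1))
    draw_flag <- function(p) stats::runif(n) < p
    per_sex <- function(spec) {
      m <- ifelse(sex == "female", spec$female[["mean"]],
                  spec$male[["mean"]])
      s <- ifelse(sex == "female", spec$female[["sd"]], spec$male[["sd"]])
      rtruncnorm_(n, m, s, spec$range[1], spec$range[2])
    }
    smoker <- draw_flag(config$rates$smoker)
    family_history <- draw_flag(config$rates$family_history)
    diabetes <- draw_flag(config$rates$diabetes)
    on_bp_medication <- draw_flag(config$rates$on_bp_medication)
    sbp_known <- draw_flag(config$rates$sbp_known)
    cholesterol_known <- draw_flag(config$rates$cholesterol_known)
    height <- per_sex(config$values$height)
    bmi <- per_sex(config$values$bmi)
    sbp <- per_sex(config$values$sbp)
    tc <- per_sex(config$values$total_cholesterol)
    data.frame(
      user_id = seq_len(n), sex = sex, age = age,
      smoker = smoker, diabetes = diabetes,
      family_history = family_history,
      on_bp_medication = on_bp_medication,
      height = round(height, 1),
      weight = round(bmi * (height / 100)^2, 1),
      sbp = ifelse(sbp_known, round(sbp), NA_real_),
      total_cholesterol = ifelse(cholesterol_known, round(tc, 1),
                                 NA_real_),
      sbp_known = sbp_known, cholesterol_known = cholesterol_known,
      stringsAsFactors = FALSE
    )
  })
}

# logistic selection with intercept solved so mean probability == p
engaged_select <- function(users, p, coefs) {
  if (p >= 1) return(rep(TRUE, nrow(users)))
  if (p <= 0) return(rep(FALSE, nrow(users)))
  eta <- rep(0, nrow(users))
  if (!is.null(coefs) && any(coefs != 0)) {
    z_age <- (users$age - mean(users$age)) /
      max(stats::sd(users$age), 1e-9)
    eta <- coefs[["age"]] * z_age +
      coefs[["sbp_known"]] * users$sbp_known +
      coefs[["cholesterol_known"]] * users$cholesterol_known
  }
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - p,
    interval = c(-30, 30), tol = 1e-10
  )$root
  stats::runif(nrow(users)) < stats::plogis(alpha + eta)
}

#' Thin a user population through the engagement funnel
#'
#' Applies two Bernoulli selection stages — report sign-up and survey
#' response — optionally weighted by age and risk-factor knowledge so
#' the engaged subsets skew older and more risk-aware, as the published
#' funnel does. Each stage's mean selection probability equals the
#' configured stage rate.
#'
#' @param users Output of [generate_users()].
#' @param config A [cohort_config()].
#' @return A list with elements `report` and `survey` (data frames,
#'   subsets of `users`).
#' @export
simulate_funnel <- function(users, config) {
  stopifnot(inherits(config, "cohort_config"))
  report <- with_substream(config$seed, 2L, function() {
    users[engaged_select(users, config$p_signup, config$engagement), ,
          drop = FALSE]
  })
  survey <- with_substream(config$seed, 3L, function() {
    if (nrow(report) == 0) return(report)
    report[engaged_select(report, config$p_survey, config$engagement), ,
           drop = FALSE]
  })
  list(report = report, survey = survey)
}

#' Simulate follow-up survey outcomes
#'
#' Draws Bernoulli outcome indicators for each survey respondent at a
#' rate specific to their heart-age category, e.g. to emulate older
#' heart-age results prompting more doctor visits. With the rates set
#' to published per-category proportions, the expected counts of the
#' simulated outcome table match the published one.
#'
#' @param survey_subset A data frame with a `category` column
#'   (`"older"`, `"younger"`, `"equal"`).
#' @param outcome_rates_by_category A named list: one entry per outcome
#'   column to create, each a named numeric vector of rates by
#'   category.
#' @param seed Integer seed (independent of the generator's streams).
#' @return `survey_subset` with one logical column added per outcome.
#' @export
simulate_survey_responses <- function(survey_subset,
                                      outcome_rates_by_category,
                                      seed = 1L) {
  stopifnot(is.data.frame(survey_subset),
            "category" %in% names(survey_subset))
  cats <- unique(survey_subset$category)
  for (nm in names(outcome_rates_by_category)) {
    rates <- outcome_rates_by_category[[nm]]
    missing <- setdiff(cats, names(rates))
    if (length(missing)) {
      stop("no ", nm, " rate configured for category: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(rates < 0 | rates > 1)) {
      stop("outcome rates must lie in [0, 1]", call. = FALSE)
    }
  }
  with_substream(seed, 4L, function() {
    for (nm in names(outcome_rates_by_category)) {
      p <- outcome_rates_by_category[[nm]][survey_subset$category]
      survey_subset[[nm]] <- stats::runif(nrow(survey_subset)) < p
    }
    survey_subset
  })
}

#' Published survey outcome counts
#'
#' The per-group outcome counts of the follow-up survey (1303
#' respondents: 1055 with an older heart-age result, 155 younger, 93
#' equal), shipped as package data. These are the observed counts the
#' chi-square comparisons are computed from; the smoking-reduction row
#' is counted among current smokers only.
#'
#' @return A data frame with one row per outcome: `outcome`,
#'   `denominator`, and yes/n counts for the older and younger-or-equal
#'   groups (plus the younger/equal split where known).
#' @export
survey_outcome_counts <- function() {
  utils::read.csv(
    system.file("extdata", "survey-outcome-counts.csv",
                package = "heartage", mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' Deterministic survey-record fixture with exact published counts
#'
#' Expands the published outcome count table into 1303 individual
#' survey records by deterministic assignment (the first k records of
#' each group get the outcome), so that [build_table2()] on the fixture
#' reproduces every published count exactly. No sampling is involved.
#'
#' @param counts An outcome count table, defaulting to
#'   [survey_outcome_counts()].
#' @return A data frame of survey records: `respondent_id`, `category`,
#'   `smoker`, and one logical column per outcome.
#' @export
table2_fixture <- function(counts = survey_outcome_counts()) {
  n_older <- max(counts$n_older[counts$denominator == "all"])
  n_younger <- max(counts$n_younger, 0, na.rm = TRUE)
  n_equal <- max(counts$n_equal, 0, na.rm = TRUE)
  n_ye <- max(counts$n_younger_equal[counts$denominator == "all"])
  if (n_younger + n_equal != n_ye) {
    stop("younger/equal split does not sum to the combined group size",
         call. = FALSE)
  }
  category <- rep(c("older", "younger", "equal"),
                  times = c(n_older, n_younger, n_equal))
  n <- length(category)
  rec <- data.frame(respondent_id = seq_len(n), category = category,
                    stringsAsFactors = FALSE)
  idx_older <- which(category == "older")
  idx_ye <- which(category != "older")  # younger block first, then equal
  n_smokers <- max(counts$n_older[counts$denominator == "smokers"], 0)
  rec$smoker <- FALSE
  rec$smoker[idx_older[seq_len(n_smokers)]] <- TRUE
  for (i in seq_len(nrow(counts))) {
    cn <- counts$outcome[i]
    v <- rep(FALSE, n)
    if (counts$denominator[i] == "smokers") {
      smokers_older <- idx_older[rec$smoker[idx_older]]
      v[smokers_older[seq_len(counts$yes_older[i])]] <- TRUE
    } else {
      v[idx_older[seq_len(counts$yes_older[i])]] <- TRUE
      if (!is.na(counts$yes_younger[i])) {
        idx_y <- which(category == "younger")
        idx_e <- which(category == "equal")
        if (counts$yes_younger[i] > 0) {
          v[idx_y[seq_len(counts$yes_younger[i])]] <- TRUE
        }
        if (counts$yes_equal[i] > 0) {
          v[idx_e[seq_len(counts$yes_equal[i])]] <- TRUE
        }
      } else if (counts$yes_younger_equal[i] > 0) {
        v[idx_ye[seq_len(counts$yes_younger_equal[i])]] <- TRUE
      }
    }
    rec[[cn]] <- v
  }
  rec
}
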