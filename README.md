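# heartage

Heart age calculation from absolute cardiovascular risk, plus the
analytics a national web-calculator evaluation needs: cohort
risk-factor summaries, chi-square comparisons of follow-up survey
outcomes, and a seeded synthetic cohort generator so the whole pipeline
runs and tests without any user data.

## Who this is for

Epidemiologists, public-health analysts and risk-communication
researchers who work with "heart age" tools: web calculators that
translate a 10-year absolute cardiovascular disease (CVD) risk into
the age at which a person with *ideal* risk-factor levels would carry
the same risk. An older heart age means at least one risk factor is
above ideal — it is a communication format, not a treatment threshold.

## The model

Risk comes from a sex-specific Framingham-type proportional-hazards
equation. For transformed covariates `x` (log age, log systolic blood
pressure with separate treated/untreated coefficients, log total and
HDL cholesterol, smoking, diabetes) with coefficients `β`:

    LP   = Σ βᵢ xᵢ
    risk = 1 − S₀ ^ exp(LP − L̄P)

where `S₀` is the baseline 10-year survival and `L̄P` the derivation
cohort's mean linear predictor. Every number is configuration data
(YAML), never hard-coded: the shipped default transcribes the
general-CVD Framingham equations (lipid-based and office/BMI-based
variants), and a deployment's recalibrated weightings drop in as a
replacement file.

Heart age inverts this risk against an ideal referent — non-smoker,
non-diabetic, systolic blood pressure 120 mmHg untreated, total
cholesterol 4.0 mmol/L — by monotone bisection of the ideal-risk
curve in age. Results are rounded to whole years (half away from
zero), categorized as younger / equal / older than the chronological
age, and censored for display at `<35` and `≥85`. Unknown blood
pressure or cholesterol values are imputed from sex- and
age-band-specific population averages; implausible inputs are blocked
with the calculator's re-entry prompt and plausible-but-high values
raise a see-your-doctor advisory without blocking.

Survey analytics use the uncorrected Pearson chi-square
`Σ(O−E)²/E` on outcome-by-heart-age-group contingency tables.

## Worked example

```r
library(heartage)
coeffs <- default_coefficients("lipid")

# a 54-year-old male smoker with diabetes who does not know his blood
# pressure or cholesterol (population averages will be used)
p <- risk_profile(54, "male", smoker = TRUE, diabetes = TRUE)
res <- calculate_heart_age(p, coeffs)
res
#> <heart_age_result> heart age ≥85 (older; raw 96.91 y), 10-year risk 34.60%
```

The raw heart age of 96.9 years means a man with ideal risk-factor
levels would not reach this user's 34.6% ten-year risk until age 97;
the display is censored at the `≥85` reporting bound and the category
is "older". The emailed-report content for this user
(`render_report(res, p)`) states the result, flags that population
averages were used, and recommends a heart health check (he is in the
45–75 target group).

Survey comparison — doctor visits among 1055 older-heart-age vs 248
younger/equal respondents:

```r
compare_outcome(c(538, 83), c(1055, 248),
                groups = c("older", "younger_equal"))
#> <outcome_comparison>
#>   older: 538/1055 (51.00%)
#>   younger_equal: 83/248 (33.47%)
#> <chi_square_result> X^2 = 24.73, df = 1, p = 6.6e-07
```

Synthetic cohort with the engagement funnel:

```r
cfg <- cohort_config(n = 10000, seed = 7)
users <- generate_users(cfg)
funnel <- simulate_funnel(users, cfg)
nrow(funnel$report); nrow(funnel$survey)
#> [1] 848
#> [1] 37
```

A command-line wrapper with `calculate`, `cohort-summary`,
`survey-compare` and `simulate` subcommands ships at
`system.file("cli", "heartage.R", package = "heartage")`.

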