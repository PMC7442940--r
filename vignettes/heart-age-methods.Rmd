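---
title: "Heart age from absolute cardiovascular risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart age from absolute cardiovascular risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartage)
```

## The risk model

The package computes 10-year absolute cardiovascular disease (CVD)
risk with a sex-specific proportional-hazards equation of the
Framingham family. Each covariate enters through a declared transform
(identity or natural log) with a regression coefficient; systolic
blood pressure (SBP) may carry separate coefficients for treated and
untreated individuals, selected by medication status. With linear
predictor $LP = \sum_i \beta_i x_i$, baseline 10-year survival $S_0$
and derivation-cohort mean $\overline{LP}$,

$$\text{risk} = 1 - S_0^{\exp(LP - \overline{LP})}.$$

The model's assumptions are those of the source equations:
proportional hazards over the 10-year horizon, log-linearity of the
continuous risk factors, and transportability of the derivation
cohort's baseline to the target population. No adjustment is made for
higher-risk subpopulations; the equation is applied as configured.

Every numeric ingredient — betas, transforms, $S_0$,
$\overline{LP}$, ideal referent levels, the family-history
multiplier — is configuration loaded from YAML
(`load_coefficients()`). This matters because deployed national
calculators recalibrate some weightings against local guidelines and
rarely publish the result; the package ships faithful transcriptions
of the published general-CVD equations (lipid-based default,
office/BMI-based alternative) and treats any recalibrated set as a
drop-in replacement file. The shipped female lipid equation was
checked against the source publication's worked example (a 61-year-old
female smoker with total cholesterol 180 mg/dL, HDL 47 mg/dL, SBP 124
untreated: 10-year risk 10.48%), which it reproduces exactly.

Two configuration conventions are worth noting:

* **Lipid units.** Users enter cholesterol in mmol/L (the clinical
  unit in Australia and most of the world); the published equations
  use mg/dL. When a coefficient set declares `lipid_units: mg/dL`,
  values are converted at 38.67 mg/dL per mmol/L before the log
  transform.
* **Reference point.** The source equations publish the overall mean
  linear predictor per sex, which the shipped configs carry as
  `mean_linear_predictor`. Per-covariate reference means (on the
  transformed scale) are also supported; when given, the mean linear
  predictor is their beta-weighted sum using the untreated-SBP beta.

### Family history and BMI

The calculator collects family history of premature heart disease,
but the published equations have no such term and the deployed tool's
handling is not public. It therefore enters as a configurable hazard
multiplier (`family_history_hazard_multiplier`, adding its log to the
linear predictor), with a deliberately neutral default of 1.0: by
default family history is recorded and reported but does not move the
score. Similarly, height and weight are always collected and BMI is
always computable (`bmi_from_height_weight()`), but BMI affects risk
only when the active coefficient set names it — the office-based
variant does; the lipid default does not.

## Heart age

Heart age answers: *at what age would a person of the same sex with
ideal risk-factor levels carry this user's absolute risk?* The ideal
referent is a non-smoker, non-diabetic, with untreated SBP 120 mmHg,
total cholesterol 4.0 mmol/L, no family history, and HDL at a
configured ideal of 1.3 mmol/L (≈50 mg/dL, a population-typical
healthy value; HDL is never user-entered, so the referent needs a
configured level — this is the one referent quantity with no
published anchor).

Because the age coefficient is positive, the referent's risk is
strictly increasing in age and the inversion is well defined. The
solver is monotone bisection on the bracket [20, 120] years with a
guaranteed tolerance of 1e-6 years; in practice iteration continues
to near machine precision (a handful of extra halvings), so the
returned age also reproduces the target risk on the ideal curve to
~1e-12. Bisection was chosen over the closed-form rearrangement —
$\ln a^* = \ln a + \Delta LP/\beta_{\text{age}}$ when age enters only
as $\beta \ln(\text{age})$ — so that coefficient sets with age
interactions remain supported; the closed form survives as an
independent test oracle, which bisection matches to well below 1e-6
years over 1000 random profiles.

Degenerate inputs never raise from the solver: a risk below the
referent's risk at age 20 (or above it at 120) clamps to the bracket
bound with a `bracket_clamped` flag.

### Rounding, category and censoring

Displayed heart ages are whole years, rounded half away from zero
(base R's `round()` rounds halves to even, which would be surprising
in a consumer-facing age). The younger/equal/older category compares
the rounded heart age with the rounded chronological age; a tie is
"equal". Display is censored at the reporting bounds — below 35
prints `<35`, at or above 85 prints `≥85` — while the raw continuous
value is always retained for analysis. Sub-ideal profiles (e.g. SBP
below 120) legitimately produce younger heart ages; no floor other
than the display bound is applied.

## Validation and imputation

Validation produces messages rather than exceptions, mirroring the
web form:

* `range_error` — implausible value; blocks calculation and prompts
  re-entry ("Please enter a number between 2 and 10.5" for
  cholesterol). Cholesterol plausibility is 2–10.5 mmol/L.
* `high_risk_advisory` — plausible but guideline-high; the heart age
  is still calculated and a pop-up urges a doctor visit (total
  cholesterol above 7.5 mmol/L).
* `eligibility_warning` — age outside the calculator's 35–75 target
  range.

The SBP plausibility range (70–250 mmHg) and high-risk threshold
(180 mmHg) are package defaults chosen to match guideline practice —
unlike the cholesterol rules they have no published anchor, and both
are configuration (`default_validation_rules()`).

Unknown SBP or cholesterol is imputed with the population mean for
the user's sex and 5-year age band; known values are never touched,
and the known/unknown flags are preserved so reports can state that
an average was used. The shipped band table
(`inst/extdata/imputation-synthetic.csv`) is **synthetic**: the
national health-survey means used by the deployed tool are not
public, so the file carries clinically plausible values and is meant
to be replaced for production use. No test or acceptance quantity
depends on its specific numbers.

## Survey analytics

Follow-up outcomes are compared across heart-age groups with the
uncorrected Pearson chi-square $\sum (O-E)^2/E$,
$(r-1)(c-1)$ degrees of freedom, two-sided upper-tail p-values —
verified to reproduce the reference comparisons from their observed
counts (e.g. doctor visits 538/1055 vs 83/248 gives 24.7 on 1 df).
Yates' correction is exposed (`correct = TRUE`) but off by default,
since the uncorrected form is what reproduces the reference values.
No multiple-testing correction is applied: these are exploratory
descriptive comparisons, and adding one would change the reported
statistics. One caveat found while verifying: the weight-loss
comparison in the reference outcome table prints 5.4 where its own
counts (537/1055 vs 106/248) give 5.35 under every applicable
statistic; the package reports the value implied by the counts.

`build_table2()` assembles the full outcome table (psychological,
lifestyle, clinical sections) grouping older vs younger-or-equal
results. The smoking-reduction row is computed among current smokers
only; rows whose table is degenerate (an empty margin) report their
counts with `NA` statistics rather than failing the whole table,
while an input containing only one heart-age group is rejected
outright.

## The synthetic cohort generator

`generate_users()` + `simulate_funnel()` emulate the three-stage
engagement funnel of a national web deployment: anonymous users, the
subset who request an emailed report, and the subset who answer a
follow-up survey. Defaults reproduce the reference deployment's
conditions — 361,044 anonymous users, sign-up probability
30,279/361,044, survey probability 1303/30,279, 61.29% female, age
bands weighted 40.00/24.63/23.08/12.29%, and the published anonymous
marginal rates for smoking (9.83%), family history (34.26%), diabetes
(5.71%), BP medication (17.85%), and BP/cholesterol knowledge
(49.38%/16.35%). Engagement is covariate-dependent: each stage is a
Bernoulli selection whose probability is logistic in standardized age
and the two knowledge flags (default coefficients 0.8/0.3/0.3, chosen
so the report-stage skew is of the order observed — engaged samples
several years older and noticeably more risk-aware), with the
intercept solved numerically so the mean selection probability equals
the stage rate. The functional form is a design choice; the reference
deployment documents the selection gradient only qualitatively.

Risk-factor values are truncated normals per sex (SBP mean 125/130
mmHg, SD 16/15, truncated to the 70–250 plausibility range; total
cholesterol 5.6/5.5 mmol/L, SD 1.0, truncated to 2–10.5; heights
162/176 cm, SD 7; BMI 27/27.5, SD 5.5/4.5, truncated 16–50 — typical
adult population moments). A single integer seed drives everything
through independent L'Ecuyer-CMRG substreams (generation, sign-up,
survey selection each get their own), so stages can be regenerated
independently and a run is exactly reproducible.

**What the generator does not emulate.** Risk factors are drawn
independently given the margins — real SBP, BMI, cholesterol, age and
medication use are correlated — and no calendar time, campaign waves
or repeat usage are modelled. Consequently the synthetic cohort's
*joint* quantities (mean heart-age gap, category shares) do not match
any real deployment's, and passing tests demonstrate correct
mechanics (marginal recovery, funnel behaviour, reproducibility), not
population realism. For exact-count outcome analytics the package
uses a different device entirely: `table2_fixture()` expands the
observed outcome counts into 1303 individual records by deterministic
assignment (no sampling), so the analytics layer can be checked
against every published count exactly.

## Problem sizes and numerical settings

The test suite and the reproduction script use: all 82 (sex × age)
ideal-profile inversions for the identity check (tolerance 0.01
years); 1000 random profiles for the closed-form comparison
(tolerance 1e-6 years); 40 seeds × 30,000 users for marginal recovery
(every configured marginal within 3 binomial SDs, required for ≥95%
of seeds); and one full-scale 361,044-user funnel. These sizes make
the Monte Carlo checks tight while keeping a complete run in the tens
of seconds.

## Known limitations

* The deployed national calculator's recalibrated weightings are not
  public; the shipped coefficient sets are the published general-CVD
  equations, so individual heart ages will differ from that tool's
  where its weightings were adjusted.
* The imputation table is a labelled synthetic stand-in (above).
* HDL's ideal level, the SBP validation thresholds and the
  family-history multiplier have no published anchors; all are
  explicit configuration with documented defaults.
* Chi-square p-values rely on the usual large-sample approximation;
  no exact test is provided (expected counts in the intended use are
  large).
* The risk equations are calibrated for ages roughly 30–74; the
  solver will evaluate the ideal curve over [20, 120] years, which is
  an extrapolation at both ends and is used only to bracket the
  inversion.
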