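Package: heartage
Title: Heart Age Calculation from Framingham-Type Absolute Cardiovascular Risk
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sex-specific 10-year absolute cardiovascular disease
    risk from configurable Framingham-style proportional-hazards equations
    and inverts it against an ideal-risk-factor referent to obtain a
    "heart age", with guideline-based input validation, imputation of
    unknown blood pressure and cholesterol from age-sex population
    averages, censored display bounds, and report assembly. Also provides
    Pearson chi-square contingency analytics for follow-up survey
    outcomes, cohort risk-factor summaries, and a seeded synthetic cohort
    generator emulating a national web calculator's engagement funnel, so
    the full pipeline is testable without any user data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
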