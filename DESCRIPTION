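Package: vaxtiming
Title: Schedule Adherence and Timeliness Analysis for Infant Vaccination Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the timeliness of multi-dose infant
    vaccination series in prospective birth cohorts. Classifies each
    infant's dose trajectory against a declarative schedule (target age
    windows, minimum ages, minimum inter-dose intervals), tabulates
    coverage by age window, estimates age-specific cumulative dose
    administration probability under standard and worst-case censoring
    assumptions via Kaplan-Meier methods, and screens demographic
    covariates against end-of-study outcomes with relative risks. Ships
    the Zambian 6-10-14 week EPI schedule as a built-in and a
    configurable stochastic cohort simulator (staggered enrolment,
    per-visit attendance and dropout, vaccine hesitancy, right-skewed
    administration delays) so every stage of the pipeline can be tested
    without access to confidential study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
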