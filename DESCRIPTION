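Package: actagree
Title: Scoring and Agreement Analysis for Domain-Specific Physical Activity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Scores a computerized physical activity questionnaire into twenty
    weekly time and energy-expenditure parameters, fuses minute-level wearable
    MET streams with an electronic activity diary into the same parameters
    (imputation, wear-time validation, bout detection, six-day weekly
    extrapolation), simulates paired cohorts from a latent weekly schedule with
    configurable self-report bias and sensor noise, and compares the two
    measurement methods with paired t-tests, Pearson correlations, Bland-Altman
    agreement analysis and gender-by-age ANOVA of difference scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
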