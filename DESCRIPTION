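Package: foodprox
Title: Continuous Food Processing Scores from Nutrient Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns NOVA food-processing classes from per-100 g nutrient
    profiles with an ensemble of random-forest classifiers, converts the
    resulting class probabilities into a continuous food processing score
    (FPro) via projection on the probability simplex, aggregates food-level
    scores into calorie- and gram-weighted individual diet scores over
    dietary recalls, ranks minimal isocaloric food substitutions within food
    categories, and runs survey-weighted association scans (EWAS-style) of
    the diet score against health outcomes with variance-stabilizing
    transforms, standardized coefficients and false-discovery-rate control.
    Includes a synthetic-data generator producing labeled food catalogs,
    dietary-recall populations and outcome tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    sandwich,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
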