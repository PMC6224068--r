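Package: dietburden
Title: Diet-Quality Scoring and the Attributable Economic Burden of
    Unhealthy Eating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the economic burden attributable to poor
    diet quality from 24-hour dietary recall surveys. Scores diets with the
    Canadian adaptation of the Healthy Eating Index 2010 (HEI-C 2010),
    estimates survey-weighted quintile distributions with balanced repeated
    replication (BRR) variance, computes population-attributable fractions
    (PAFs) across multiple exposure levels with Monte-Carlo confidence
    intervals, and attributes direct health-care and indirect costs to
    unhealthy eating by disease, sex, age group, and survey year, with
    sensitivity bounds from the relative-risk confidence intervals. Includes
    a synthetic cohort generator emulating two nutrition-survey cycles with
    replicate sampling weights so the full pipeline is testable without
    restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
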