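Package: labelrct
Title: Desk-Scale Engine for Fully Automated Nutrition-Labeling Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A library that conducts a fully automated nutrition-labeling
    randomized controlled trial at desk scale: informed consent, two-stage
    eligibility checking, server-style stratified blocked randomization with
    variable block sizes, a timeline-driven participant lifecycle, a
    notification and reminder rule engine, barcode-keyed intervention delivery
    in five front-of-pack label formats (Daily Intake Guide, Traffic Lights,
    Health Star Rating, Nutrition Information Panel, Warning Label), and
    electronic shopping-data capture. A synthetic participant-cohort simulator
    exercises the whole engine end-to-end and produces recruitment-funnel and
    usage reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
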