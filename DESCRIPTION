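Package: pluscore
Title: Hierarchical Fuzzy Scoring and Monitoring of Life Satisfaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the PLUS (personal living usual satisfaction)
    composite score: a three-tier hierarchical Mamdani fuzzy-inference
    system that aggregates the Perceived Stress Scale (PSS10), the
    Satisfaction with Life Scale (SWLS), the Nordic Musculoskeletal
    Questionnaire (NMQ) and the three Maslach Burnout Inventory subscales
    into a single life-satisfaction score on the unit interval, using
    trapezoidal membership functions, product premise aggregation, min
    implication, max accumulation and exact centre-of-gravity
    defuzzification. Includes longitudinal deterioration detection, group
    summary statistics, change-score Spearman correlations, a seeded
    synthetic-cohort generator, validated records input/output,
    model-definition serialization and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
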