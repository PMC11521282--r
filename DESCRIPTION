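Package: hipcea
Title: Cost-Effectiveness Microsimulation of Surgical Options for
    Displaced Femoral Neck Fractures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov state-transition model comparing
    bipolar hemiarthroplasty (BHA), single-bearing total hip arthroplasty
    (SB-THA) and dual-mobility THA (DM-THA) for displaced femoral neck
    fractures in active older patients, from the Japanese public healthcare
    payer's perspective. Provides a first-order Monte Carlo microsimulation
    with a dislocation tracker, a deterministic cohort-expectation
    evaluator, incremental cost-effectiveness and dominance analysis,
    one-way sensitivity analysis with willingness-to-pay threshold search,
    probabilistic sensitivity analysis with acceptability curves and
    confidence ellipses, and age/sex/horizon scenario grids. Ships a
    transcribed model parameter table and synthetic sex-specific life
    tables so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
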