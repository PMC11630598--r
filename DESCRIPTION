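Package: bariaCEA
Title: Cost-Utility and Budget Impact Modelling of Bariatric Surgery in
    Obesity with Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort model comparing laparoscopic bariatric
    surgery with non-surgical care for patients with obesity and type 2
    diabetes mellitus, evaluated from payer and societal perspectives in the
    Thai setting. Implements cycle-indexed diabetes remission and relapse
    transitions, obesity-related complication states (myocardial infarction
    with a first-year tunnel, stroke, congestive heart failure, chronic
    kidney disease), background mortality via a rate-ratio-adjusted life
    table, discounted cost/QALY accumulation and ICER comparison, one-way
    (tornado) and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, a five-year budget impact projection from a
    national eligible-population cascade, and a synthetic patient-level data
    generator for end-to-end testing without access to the source cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
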