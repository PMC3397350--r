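Package: zincsim
Title: Simulation of Dietary Zinc Intake Under Rice Biofortification Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate the effect of zinc-biofortified rice on
    population zinc intake in a dietary-survey cohort. Generates synthetic
    survey cohorts with configurable demographic margins, rice-intake and
    zinc-intake distributions and a latent-factor food-frequency structure;
    computes zinc and energy intake from recall-style food quantities and a
    food-composition table; scores dietary patterns from published factor
    loadings and assigns quartiles; substitutes biofortified rice at
    configurable zinc concentrations; and classifies intakes against Chinese
    dietary reference values (insufficient, excess, absorbed-zinc
    inadequacy), with scenario summaries, quartile-stratified tables and
    paired-comparison and trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
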