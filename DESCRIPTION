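Package: metanor
Title: Enteric Methane Prediction and National-Inventory Emission Factors
    for Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-tier modelling chain for enteric methane (CH4) from dairy
    cows. A basic tier predicts daily CH4 production (MJ/day) from dry
    matter intake and dietary fatty-acid and neutral-detergent-fiber
    concentrations, with a registry of published fixed-coefficient
    equations, weighted linear mixed-effects refitting on feeding-trial
    treatment means (random study intercept), variance-inflation and
    measurement-technique screening, and model evaluation by mean squared
    prediction error decomposition and Lin's concordance correlation
    coefficient. An operational tier simulates a NorFor-style feeding
    database over 305-day lactations, derives the methane conversion
    factor Ym (% of gross energy intake) and gross energy intake from
    energy-corrected milk yield and dietary concentrate share, and
    composes IPCC Tier-2 style annual emission factors (kg CH4/head/year).
    Includes a seeded synthetic feeding-trial generator for parameter
    recovery and ranking studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
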