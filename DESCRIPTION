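Package: fallclass
Title: Latent Class Modelling of Fall Risk from Medication and Morbidity Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-step modelling of falls in community-dwelling elderly
    populations. Prescription medications are scored by correspondence
    analysis of the medication-by-fall contingency table and averaged into a
    per-patient drug falling measure; a latent class model with seven binary
    morbidity indicators and the Gaussian drug measure, concomitant
    covariates (age, gender, number of medications) and a distal fall
    outcome is then estimated by expectation-maximisation. Model selection
    uses BIC, relative entropy, pattern goodness-of-fit statistics and a
    parametric bootstrap likelihood ratio test; results are reported as
    classification tables, class profiles and distal-outcome odds ratios.
    A configurable synthetic cohort generator provides test beds with known
    class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
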