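Package: volemu
Title: Target Trial Emulation for Surgeon and Hospital Operative Volume
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study volume-outcome questions in surgery with the
    target-trial framework. Generates synthetic operation-level claims data
    from an explicit structural causal model (right-skewed provider volumes,
    travel-time-dependent provider selection, latent provider quality,
    patient-severity confounding, 90-day mortality), emulates four target
    trials with increasingly well-defined volume interventions (surgeon
    volume; joint surgeon and hospital volume; driving-time-constrained
    strategies with natural values of treatment beyond the threshold; double
    randomization to providers within volume levels), estimates standardized
    mortality risks and risk differences by plug-in g-formula over a logistic
    outcome model, quantifies uncertainty with a nonparametric cluster
    bootstrap, and compares every design against the generator's true
    counterfactual risks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
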