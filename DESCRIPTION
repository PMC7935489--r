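Package: arbitrium
Title: Eco-Evolutionary Dynamics of Temperate Phage Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic modelling of the lysis-lysogeny decision in
    temperate bacteriophages that communicate through a secreted
    signalling peptide (the "arbitrium" system). Implements a scaled
    ODE system of susceptible bacteria, lysogens, multi-variant free
    phages and the peptide concentration; serial-passaging drivers with
    mutation-selection on the lysogeny propensity and response
    threshold; closed-form and numerical evolutionarily-stable-strategy
    (ESS) calculators; equilibrium finding and classification; and
    randomized parameter sweeps. Episode integration uses compiled
    derivatives through 'deSolve'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
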