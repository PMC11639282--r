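Package: wexchange
Title: Substrate-Water Exchange Kinetics of Photosystem II from TR-MIMS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting of substrate-water (16O/18O) exchange
    experiments on the S2 state of photosystem II as measured by
    time-resolved membrane-inlet mass spectrometry (TR-MIMS). Implements the
    two-site, two-conformation kinetic scheme as a continuous-time master
    equation over eight isotopologue states, its closed-form eigen-structure
    (including the slow eigenvalue pair and its approximation regimes),
    measurement corrections for non-zero initial enrichment, non-instant
    injection/mixing, and S3-state carryover exchange, the classical bi- and
    tri-exponential empirical yield models, chi-square fitting with
    multi-start bounded least squares, and bootstrap parameter uncertainty.
    Ships the published rate-constant presets and a synthetic-data generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
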