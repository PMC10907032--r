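Package: cardpes
Title: Cardiac Action Potential Modelling and Virtual Programmed Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal human ventricular action potential model with disease
    (heart failure) and drug (amiodarone, d-sotalol) parameterizations, clinical
    calibration machinery (action potential duration, maximal upstroke velocity,
    post-repolarization refractoriness), virtual S1-S4 programmed electrical
    stimulation in single cells, 1-D cables and 2-D monodomain sheets with
    pyramidic parameter gradients, and classification of reentry induction
    outcomes (extra beats, tachycardia, fibrillation, wave break) via phase
    singularity tracking. Simulation kernels are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
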