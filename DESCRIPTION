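Package: mikana
Title: Gene Regulatory Network Inference from Steady-State and Time-Series
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: ODE-regression inference of gene regulatory networks from
    steady-state knockdown data (ssMIKANA), time-series data (tsMIKANA),
    or both combined (cMIKANA). Each gene's rate of change is modelled as
    a weighted sum of Hill basis functions of candidate regulators minus
    first-order degradation; regulators are chosen per target gene by
    iterative forward-backward subset selection under a description-length
    cost. Includes a scale-free network generator, a saturating-kinetics
    expression simulator (reference steady states, siRNA knockdowns,
    perturbation time courses, multiplicative Gaussian measurement noise),
    edge-wise scoring (sensitivity, false discovery rate, directionality),
    and drivers for noise-sweep, sample-budget and edge-direction
    simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
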