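Package: plastidyn
Title: Population Dynamics of Epithelial-Mesenchymal Phenotypic Plasticity Under Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartment model of a phenotypically plastic tumor cell
    population distributed along the epithelial-mesenchymal axis. N phenotype
    compartments grow logistically under a shared carrying capacity, with biased
    nearest-neighbour phenotype transitions, and are subject to growth-dependent
    (chemotherapy-like) or growth-independent (immunotherapy-like) treatment.
    Provides the closed-form coexistence equilibrium and its moments, linear
    stability analysis via the analytic Jacobian, numerical integration over
    single-block, alternating and adaptive treatment schedules, calibration of the
    growth-independent treatment intensity, the treatment decision boundary in the
    transition bias, burden-reduction sweeps over transition bias and speed, and
    adjuvant parameter-shift comparisons.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
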