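Package: cvscalib
Title: Automated Calibration of Lumped-Parameter Cardiovascular Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Task-specific calibration of closed-loop lumped-parameter (0D)
    cardiovascular system models. Provides a compiled forward simulator of a
    modular heart-valve-artery-terminal-vein circulation, finite-difference
    sensitivity analysis with parameter-importance and collinearity indices
    for iterative structural-identifiability reduction of the fitting
    parameter set, a real-coded genetic algorithm for box-bounded fitting,
    an affine-invariant ensemble Markov chain Monte Carlo sampler with
    Geweke convergence diagnostics, and posterior-sampled uncertainty
    quantification of a core prediction (middle cerebral artery pressure).
    A synthetic-patient generator emulating clinical measurement sets with
    realistic coefficients of variation makes the whole pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
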