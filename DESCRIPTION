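Package: spindlenuc
Title: Autocatalytic Microtubule Nucleation, Laser-Ablation Wave Analysis,
    and Spindle-Size Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spatially regulated, microtubule-stimulated
    (autocatalytic) microtubule nucleation in radially symmetric spindle-like
    structures. Implements a closed-form steady-state model of filament density
    under a gradient of active nucleators, with parameter fitting, a
    parameter-free rescaling between conditions, and growth-regime
    classification; a stochastic agent-based simulator of the nucleator-filament
    reaction-diffusion system (gradient, uniform-activation, obstacle, and
    independent-nucleation modes); the laser-ablation depolymerization-wave
    analysis that recovers depolymerization velocity, minus-end densities,
    per-area nucleation profiles, and microtubule length distributions from
    post-cut movies or radial profile stacks; maximum-likelihood fitting of
    speckle lifetime distributions with a drift-diffusion first-passage form;
    and ground-truth synthetic data generators (parametric monopoles, rendered
    image stacks, cut fixtures, speckle tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
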