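Package: gmma
Title: Global Multi-Method Analysis of Biomolecular Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Global multi-method analysis (GMMA) of biomolecular binding
    data: one thermodynamic interaction model is fitted simultaneously to
    heterogeneous data sets from isothermal titration calorimetry (ITC),
    surface plasmon resonance (SPR) steady-state and competition isotherms,
    sedimentation velocity signal-weighted s_w isotherms, fluorescence
    anisotropy titrations and generic linear spectroscopy. Provides a
    mass-action equilibrium solver for multi-site models (macroscopic or
    microscopic-with-cooperativity parameterizations), per-technique
    forward models with local nuisance parameters (concentration errors,
    incompetent fractions, baselines), a weighted global chi-square
    objective minimized by Marquardt-Levenberg, simplex or simulated
    annealing, post-fit statistics (covariance and cross-correlations,
    F-statistics error-surface projections, Monte-Carlo intervals, weight
    scans, cross-validation consistency tests), and experimental-design
    tools that map signal and species populations over concentration
    space, crop them by stock and signal feasibility, sample
    log-equidistant titration trajectories, emit mixing recipes and
    simulate data sets in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
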