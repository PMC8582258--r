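Package: fluqfit
Title: Fluctuating-Charge Force-Field Parametrization and Solvatochromic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parametrizing fluctuating-charge (FQ) polarizable
    force fields for molecular solvents and for analysing solvatochromic
    shifts of solvated chromophores.  Implements the
    electronegativity-equalization charge model (constrained charge
    solver, interaction energies, static polarizability tensors), the
    dipolar-probe reference-scan geometry, a distance-weighted
    mean-squared-error loss fitted by a bounded real-coded genetic
    algorithm with multiple restarts, physical validation of candidate
    parameter sets (electronegativity ordering, molecular and bulk
    polarizability agreement), snapshot extraction and solute-centered
    sphere clipping of solvated configurations, and excitation-ensemble
    analysis (corrected-linear-response energy combination,
    solvatochromic shifts, Gaussian band fitting and full width at half
    maximum, polarity-trend regression).  Synthetic-data generators make
    every stage testable without external quantum-chemistry or
    molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    tools
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
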