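Package: abfekit
Title: Desk-Scale Toolkit for Absolute Binding Free Energy Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engine-agnostic computational core of restraint-based absolute
    binding free energy (ABFE) workflows in the style of the BAT2 program:
    ligand and protein anchor-atom selection from structures, Boresch-style
    translational/rotational restraints with analytic standard-state release,
    free-energy estimators (MBAR, BAR, thermodynamic integration with
    Gaussian quadrature, finite-difference dU/dlambda), block-analysis and
    replica uncertainties, and thermodynamic-cycle assembly for split
    (double-decoupling) and merged (simultaneous decoupling-recoupling)
    schemes. A Metropolis Monte-Carlo toy sampler with analytically known
    free energies stands in for molecular dynamics so every stage of the
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
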