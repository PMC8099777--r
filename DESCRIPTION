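Package: ptmladder
Title: Fragment Assignment, PTM Localization and Positional-Isomer
    Quantification for Top-Down ETD Spectra
Version: 0.1.0
Authors@R: person("ptmladder", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyses deconvoluted electron-transfer-dissociation (ETD)
    fragmentation spectra of intact proteins. Theoretical c/z-type (and
    related) neutral fragment masses are matched to deisotoped peak lists
    with data-driven ppm recalibration, fragment-level false discovery
    rate estimation against scrambled decoy sequences, data-driven ion
    type selection, and majority voting across technical replicates.
    Accepted fragments are arranged into per-terminus PTM ladders from
    which modification sites are localized with a binomial
    stretch-probability score, and the stoichiometry of co-isolated
    positional isomers is quantified from modified/unmodified fragment
    intensity ratios via a constrained non-negative least-squares system,
    with grouped reporting when the system is rank deficient. A seeded
    simulator generates deconvoluted spectrum sets for proteoform
    mixtures with full ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    MASS,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
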