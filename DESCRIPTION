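Package: foldcv
Title: Bottom-Up Collective Variables for Protein Folding Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, bottom-up construction of two bioinspired collective
    variables (CVs) for enhanced-sampling simulations of protein folding: a
    hydrogen-bond CV that distinguishes protein-protein from protein-water
    interactions (with angular terms) and a side-chain packing CV built from
    distances between side-chain centers of mass.  Candidate contacts are
    harvested from two short unbiased end-state trajectories (one folded, one
    unfolded), classified as native or non-native, filtered with a Fisher
    (LDA-like) discriminant, and summed with coefficients +1 (native) and -1
    (non-native).  The package evaluates the CVs on trajectories, emits PLUMED
    input files, and implements the accompanying folding-landscape analysis
    protocol: C-alpha RMSD, hysteretic dual-cutoff state assignment, transition
    counting and residence times, folding free-energy and enthalpy differences,
    free-energy surfaces with reweighting, and multi-replica aggregation.
    Self-contained synthetic two-state peptide-in-water fixtures with planted
    contacts and known thermodynamics are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
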