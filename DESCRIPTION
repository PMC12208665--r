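Package: mcligand
Title: Multiconformer Ligand Modeling in Real-Space Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and models alternate ligand conformations in
    crystallographic and cryo-EM density maps. Starting from a
    single-conformer ligand, a SMILES bond-order template and a real-space
    map, the package generates constrained conformer ensembles with biased
    torsion sampling, estimates conformer occupancies by quadratic
    programming against the observed density, selects a parsimonious
    multiconformer model (up to three conformers for X-ray, two for
    cryo-EM) by cardinality-constrained mixed-integer quadratic
    programming, and validates the result with real-space correlation,
    per-atom electron-density support (EDIA) and coordinate RMSD. A
    synthetic-density benchmark generator reproduces a two-conformer
    ground-truth grid over occupancy splits and map resolutions so the
    whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
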