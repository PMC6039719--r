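Package: xlscore
Title: Crosslink and Density Based Scoring of Protein Complex Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores models of protein complexes against crosslinking
    mass-spectrometry restraints using the cMNXL score, built on a
    voxel-grid solvent-accessible surface distance (SASD) engine with a
    Euclidean-distance variant. Includes ground-truth model quality
    metrics (per-subunit mean C-alpha RMSD and fnat), a benchmark
    evaluation protocol (top-10 precision and false-positive rate with
    tie bootstrapping, ROC/AUC, crosslink recovery sampling, term-weight
    scanning, paired significance tests), simulated 3D-EM density maps
    with a mutual-information plus clash-penalty fitness score, a
    combined crosslink + density score, and generators for synthetic toy
    complexes and rigid-body decoy ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
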