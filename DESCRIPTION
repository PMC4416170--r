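Package: poseforge
Title: RMSD-Response Machine-Learning Scoring Functions for Docking Pose
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating machine-learning scoring
    functions that identify native ligand binding poses among docking
    decoys. Implements geometrical protein-ligand atom-pair count
    descriptors (36 element pairs within 12 Angstroms, and a five-bin
    180-feature extension), RMSD-based decoy-set construction (filtering,
    1 Angstrom binning, complete-linkage clustering and lowest-energy
    representative selection), six regression scoring functions (multiple
    linear regression, multivariate adaptive regression splines,
    k-nearest neighbours, support vector machines, random forests and
    boosted regression trees) trained with either binding affinity or
    RMSD as the response, docking-power success-rate statistics over
    cutoff/depth grids, similarity-constrained train/test splitting for
    novel-target evaluation, and a synthetic complex generator so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    Biostrings,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
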