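Package: topoland
Title: Structural Feature Landscapes of Cytoplasmic and Exported Proteomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Proteome-wide comparison of the structural properties of
    cytoplasmic versus exported and secreted bacterial proteins. Computes
    per-protein sequence features (residue-set composition, GRAVY hydropathy,
    isoelectric point, biosynthetic cost, hydrophobic patches), segments
    per-residue predictor tracks into intrinsically disordered regions, early
    foldons and aggregation-prone regions with gatekeeper analysis, derives
    relative contact order and termini distance from atomic coordinates,
    censuses the fold repertoire across subcellular topology groups, scores
    protein abundance variability across growth conditions, runs the group
    comparison statistics, and trains a cross-validated cytoplasmome-versus-
    secretome classifier with feature-family ablations. A synthetic proteome
    generator with planted ground truth makes every stage testable without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    bio3d,
    glmnet,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
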