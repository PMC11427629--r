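Package: surfbind
Title: Prediction of Nucleic-Acid Binding from Protein Molecular Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts nucleic-acid binding function (whole-protein
    classification) and binding sites (per-vertex and per-residue
    segmentation) from geometric, chemical and electrostatic features
    mapped onto a triangulated protein molecular-surface mesh. Provides
    PDB parsing, Gaussian-density isosurface mesh generation, OFF/PLY
    import and export, a structural vertex-feature set (electrostatic
    potential and field, Atchley factors, spatial aggregation propensity,
    hydrogen-bond donors and acceptors, circular variance, mean curvature,
    heat kernel signatures) plus PSSM/HMM profile parsing, graph neural
    networks with farthest-point-sampling pooling and k-nearest-neighbour
    unpooling built on crystal-graph convolutions, training with
    cross-validation, Platt calibration and thresholding, and model
    attribution by grouped feature permutation and Grad-CAM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    bio3d
Config/testthat/edition: 3
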