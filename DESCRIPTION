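Package: cgrf
Title: Clustering Genetic Random Forest for Voxel-Based Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An evolutionary ensemble classifier for subject-by-voxel
    feature tables such as hippocampal voxel intensities extracted from
    structural MRI. Decision trees grown by CART are bred across
    generations: parents are selected within random groups by pairing the
    most accurate tree with the tree most behaviourally distant from it
    (clustering-based selection), offspring are produced by subtree
    crossover, and the best two of four candidates survive each round.
    Includes frequency-based voxel importance extraction with a
    subset-size sweep, baseline forest variants for comparison, grid
    tuning over forest size and generations, NIfTI volume down-sampling
    and mask-based feature extraction, and a synthetic data generator
    with planted informative voxels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
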