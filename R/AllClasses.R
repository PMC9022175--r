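#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' VoxelExperiment: labelled subject-by-voxel dataset
#'
#' A \linkS4class{SummarizedExperiment} whose assay holds voxel intensities
#' (rows = voxels, columns = subjects) and whose \code{colData} carries the
#' class label of each subject, coded AD = -1 and HC = +1. Row names are the
#' stable voxel identifiers; column names the subject identifiers.
#'
#' @slot .. inherited from SummarizedExperiment; the single assay is named
#'   \code{"voxels"}.
#' @seealso [VoxelExperiment()] for construction, [featureMatrix()],
#'   [subjectLabels()], [voxelIds()] for access.
#' @export
setClass("VoxelExperiment", contains = "SummarizedExperiment")

setValidity("VoxelExperiment", function(object) {
  a <- assay(object)
  if (!is.numeric(a)) return("assay must be numeric")
  if (anyNA(a) || any(!is.finite(a))) return("assay has missing/non-finite values")
  if (!"label" %in% colnames(colData(object))) return("colData must have a 'label' column")
  lab <- colData(object)$label
  if (!all(lab %in% c(-1, 1))) return("labels must be coded -1 (AD) / +1 (HC)")
  if (ncol(a) > 0 && length(unique(lab)) < 2)
    return("both classes (-1 and +1) must be present")
  if (is.null(rownames(object))) return("voxel identifiers (rownames) required")
  TRUE
})

#' DataSplit: train/validation/test partition of subjects
#'
#' Index sets produced by [splitDataset()] under the 6:2:2 rule. The three
#' parts are pairwise disjoint and cover all subjects.
#'
#' @slot train,val,test integer subject indices (1-based).
#' @slot seed the integer seed that produced the permutation.
#' @export
setClass("DataSplit",
  representation(train = "integer", val = "integer", test = "integer",
                 seed = "integer"))

setValidity("DataSplit", function(object) {
  all_idx <- c(object@train, object@val, object@test)
  if (anyDuplicated(all_idx)) return("split parts overlap")
  if (!setequal(all_idx, seq_along(all_idx))) return("split parts must cover 1..n")
  TRUE
})

#' DecisionTree: a binary CART classification tree
#'
#' Nodes are stored as a flat table (row 1 = root) with columns
#' \code{feature} (voxel column index; 0 at leaves), \code{threshold}
#' (go left iff value <= threshold), \code{left}/\code{right} (child row
#' ids; 0 at leaves) and \code{label} (-1/+1 at leaves).
#'
#' @slot nodes numeric node table as above.
#' @slot featurePool sorted integer voxel indices this tree may split on.
#' @slot nFeatures total number of voxel columns in the dataset.
#' @slot seed integer seed used to draw the pool and row subsample.
#' @export
setClass("DecisionTree",
  representation(nodes = "matrix", featurePool = "integer",
                 nFeatures = "integer", seed = "integer"))

setValidity("DecisionTree", function(object) {
  nd <- object@nodes
  need <- c("feature", "threshold", "left", "right", "label")
  if (!all(need %in% colnames(nd))) return("node table missing columns")
  internal <- nd[, "feature"] != 0
  if (any(internal & !is.finite(nd[, "threshold"])))
    return("internal nodes need finite thresholds")
  if (any(nd[internal, "feature"] > object@nFeatures))
    return("split feature out of range")
  if (length(object@featurePool) &&
      !all(nd[internal, "feature"] %in% object@featurePool))
    return("split on a feature outside the tree's pool")
  if (!all(nd[!internal, "label"] %in% c(-1, 1)))
    return("leaf labels must be -1/+1")
  TRUE
})

#' TreeForest: an ordered ensemble of decision trees
#'
#' @slot trees list of \linkS4class{DecisionTree}.
#' @slot seed integer seed that built the forest.
#' @export
setClass("TreeForest", representation(trees = "list", seed = "integer"))

setValidity("TreeForest", function(object) {
  if (length(object@trees) < 1) return("forest must contain at least one tree")
  if (!all(vapply(object@trees, is, logical(1), "DecisionTree")))
    return("all elements must be DecisionTree objects")
  TRUE
})

#' EvaluationReport: accuracy of a predictor on an evaluation set
#'
#' @slot accuracy fraction of correct predictions, nCorrect / nEval.
#' @slot nCorrect,nEval integer counts.
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric", nCorrect = "integer", nEval = "integer"))

setValidity("EvaluationReport", function(object) {
  if (object@nEval < 1) return("empty evaluation set")
  if (!isTRUE(all.equal(object@accuracy, object@nCorrect / object@nEval)))
    return("accuracy must equal nCorrect / nEval")
  TRUE
})

#' SimilarityMatrix: pairwise tree distances within a candidate group
#'
#' Strictly upper-triangular g-by-g matrix of Euclidean distances between
#' the trees' prediction vectors on the validation set; the diagonal and
#' lower triangle are zero.
#'
#' @slot entries numeric g x g matrix.
#' @slot groupIndices the population indices of the g trees.
#' @export
setClass("SimilarityMatrix",
  representation(entries = "matrix", groupIndices = "integer"))

setValidity("SimilarityMatrix", function(object) {
  e <- object@entries
  if (nrow(e) != ncol(e)) return("entries must be square")
  if (nrow(e) != length(object@groupIndices))
    return("groupIndices length must match matrix size")
  if (any(e[lower.tri(e, diag = TRUE)] != 0))
    return("diagonal and lower triangle must be zero")
  if (any(e < 0)) return("distances must be non-negative")
  TRUE
})

#' EvolutionConfig: parameters of a clustering genetic random forest run
#'
#' @slot nTrees forest size (default 300).
#' @slot generations number of full population rebuilds.
#' @slot groupSize trees per candidate group (default 5).
#' @slot groupsPerRound candidate groups drawn per breeding round (default 2).
#' @slot offspringPerRound offspring retained per round (default 2), so one
#'   generation takes nTrees / offspringPerRound rounds.
#' @slot mFeatures features drawn per tree; NA means floor(sqrt(p)).
#' @slot sampleFraction bootstrap fraction of training rows per tree.
#' @slot maxDepth tree depth cap.
#' @slot minSamplesLeaf minimum samples per leaf.
#' @slot distanceOn "predictions" (validation prediction vectors) or
#'   "features" (0/1 voxel-usage indicator vectors) as the space for the
#'   tree-distance metric.
#' @slot seed root seed.
#' @export
setClass("EvolutionConfig",
  representation(nTrees = "integer", generations = "integer",
                 groupSize = "integer", groupsPerRound = "integer",
                 offspringPerRound = "integer", mFeatures = "integer",
                 sampleFraction = "numeric", maxDepth = "integer",
                 minSamplesLeaf = "integer", distanceOn = "character",
                 seed = "integer"))

setValidity("EvolutionConfig", function(object) {
  if (object@nTrees < 1) return("nTrees must be >= 1")
  if (object@generations < 0) return("generations must be >= 0")
  if (object@groupSize < 2) return("groupSize must be >= 2")
  if (object@nTrees %% object@offspringPerRound != 0)
    return("nTrees must be divisible by offspringPerRound")
  if (object@generations > 0 &&
      object@groupsPerRound * object@groupSize > object@nTrees)
    return("population too small for groupsPerRound disjoint groups")
  if (!object@distanceOn %in% c("predictions", "features"))
    return("distanceOn must be 'predictions' or 'features'")
  if (object@sampleFraction <= 0) return("sampleFraction must be > 0")
  TRUE
})

#' EvolutionResult: outcome of an evolutionary forest run
#'
#' @slot bestForest the forest snapshot with maximal validation accuracy.
#' @slot bestGeneration generation index of that snapshot (0 = initial).
#' @slot history ensemble validation accuracy per generation, starting at
#'   generation 0.
#' @slot testAccuracy accuracy of bestForest on the held-out test set.
#' @slot variant one of "rf", "gerf", "cerf", "cgrf".
#' @slot config the \linkS4class{EvolutionConfig} used.
#' @slot roundLog one row per breeding round: generation, round, the four
#'   parent population indices, and the four candidate offspring accuracies.
#' @export
setClass("EvolutionResult",
  representation(bestForest = "TreeForest", bestGeneration = "integer",
                 history = "numeric", testAccuracy = "numeric",
                 variant = "character", config = "EvolutionConfig",
                 roundLog = "data.frame"))

setValidity("EvolutionResult", function(object) {
  h <- object@history
  if (length(h) < 1) return("history must be non-empty")
  bg <- object@bestGeneration
  if (bg < 0 || bg + 1 > length(h)) return("bestGeneration out of history range")
  if (h[bg + 1] != max(h)) return("bestGeneration must attain max(history)")
  TRUE
})

#' VoxelMask: ordered in-mask coordinates of one hemisphere
#'
#' @slot coords integer n x 3 matrix of (i, j, k) voxel coordinates
#'   (1-based), ordered lexicographically.
#' @slot hemisphere "left" or "right".
#' @slot voxelIds stable identifiers, one per coordinate.
#' @slot gridShape the 3-D grid the coordinates live in.
#' @export
setClass("VoxelMask",
  representation(coords = "matrix", hemisphere = "character",
                 voxelIds = "character", gridShape = "integer"))

setValidity("VoxelMask", function(object) {
  cc <- object@coords
  if (ncol(cc) != 3) return("coords must have 3 columns")
  if (nrow(cc) == 0) return("mask is empty")
  if (anyDuplicated(cc)) return("coordinates must be unique")
  if (length(object@voxelIds) != nrow(cc))
    return("one voxel id per coordinate required")
  if (any(cc < 1) || any(cc > matrix(object@gridShape, nrow(cc), 3, byrow = TRUE)))
    return("coordinates outside grid")
  ord <- order(cc[, 1], cc[, 2], cc[, 3])
  if (!identical(ord, seq_len(nrow(cc))))
    return("coordinates must be in lexicographic (i, j, k) order")
  if (!object@hemisphere %in% c("left", "right"))
    return("hemisphere must be 'left' or 'right'")
  TRUE
})

#' ImportanceResult: voxel-frequency ranking and subset-sweep outcome
#'
#' @slot ranking data.frame with columns voxel_id, voxel_index, frequency,
#'   sorted by descending frequency (ties: lower voxel index first).
#' @slot subsetSizes integer subset sizes evaluated by the sweep.
#' @slot subsetAccuracies validation accuracy at each size.
#' @slot selectedSize peak-accuracy size (ties: smallest).
#' @slot selectedVoxels the top-selectedSize voxel ids.
#' @slot testAccuracy test-set accuracy of the selected subset's forest.
#' @slot nF number of abnormal voxels chosen (0 if not yet chosen).
#' @slot abnormalVoxels top-nF voxel ids within the selected subset.
#' @export
setClass("ImportanceResult",
  representation(ranking = "data.frame", subsetSizes = "integer",
                 subsetAccuracies = "numeric", selectedSize = "integer",
                 selectedVoxels = "character", testAccuracy = "numeric",
                 nF = "integer", abnormalVoxels = "character"))

setValidity("ImportanceResult", function(object) {
  r <- object@ranking
  if (nrow(r) && is.unsorted(-r$frequency)) return("ranking must be descending")
  if (length(object@subsetSizes) != length(object@subsetAccuracies))
    return("one accuracy per subset size required")
  if (length(object@selectedSize) && nrow(r) &&
      !all(object@selectedVoxels == r$voxel_id[seq_len(object@selectedSize)]))
    return("selected subset must be a prefix of the ranking")
  if (!all(object@abnormalVoxels %in% object@selectedVoxels))
    return("abnormal voxels must lie within the selected subset")
  TRUE
})
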