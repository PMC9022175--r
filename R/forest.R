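#' Default per-tree feature count
#'
#' floor(sqrt(p)) features are drawn for each tree, the classic random
#' forest heuristic; with the 583 hippocampal voxels this gives 24.
#'
#' @param p total number of voxel features.
#' @return integer.
#' @export
defaultMFeatures <- function(p) as.integer(floor(sqrt(p)))

#' Train a single CART decision tree
#'
#' One tree of the forest: a seeded feature pool of `mFeatures` voxels is
#' drawn once for the whole tree, a seeded bootstrap of training rows is
#' taken, and a binary CART tree is grown by greedy Gini-impurity
#' minimisation over that pool. Candidate thresholds are midpoints between
#' consecutive distinct sorted values; ties in impurity are broken by lower
#' feature index, then lower threshold. Growth stops at node purity,
#' `minSamplesLeaf`, or `maxDepth`; leaves take the majority label of their
#' routed rows (ties -> +1).
#'
#' @param X numeric training matrix (subjects x voxels).
#' @param y labels in \{-1, +1\}.
#' @param mFeatures features per tree; default floor(sqrt(ncol(X))).
#' @param sampleFraction bootstrap fraction of rows, drawn with
#'   replacement (default 1).
#' @param seed integer seed for pool and subsample.
#' @param maxDepth,minSamplesLeaf stopping parameters.
#' @return a \linkS4class{DecisionTree}.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' y <- ifelse(X[, 2] > 0, 1, -1)
#' tr <- trainTree(X, y, mFeatures = 4L, seed = 1)
#' mean(predict(tr, X) == y)
#' @export
trainTree <- function(X, y, mFeatures = defaultMFeatures(ncol(X)),
                      sampleFraction = 1, seed = 0L, maxDepth = 20L,
                      minSamplesLeaf = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("one label per row required")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  if (mFeatures < 1 || mFeatures > ncol(X))
    stop("mFeatures must be in [1, ncol(X)]")
  drawn <- withSeed(seed, {
    pool <- sort(sample.int(ncol(X), mFeatures))
    rows <- sample.int(nrow(X), size = max(1L, round(sampleFraction * nrow(X))),
                       replace = TRUE)
    list(pool = pool, rows = rows)
  })
  ysub <- y[drawn$rows]
  if (length(unique(ysub)) < 2) {
    warning("single-class training subsample; returning a one-leaf tree")
    nodes <- matrix(c(0, NA, 0, 0, if (sum(ysub > 0) >= sum(ysub < 0)) 1 else -1),
                    1, 5, dimnames = list(NULL,
                    c("feature", "threshold", "left", "right", "label")))
  } else {
    nodes <- cpp_grow_tree(X[drawn$rows, , drop = FALSE], ysub,
                           as.integer(drawn$pool), as.integer(maxDepth),
                           as.integer(minSamplesLeaf))
  }
  new("DecisionTree", nodes = nodes, featurePool = as.integer(drawn$pool),
      nFeatures = ncol(X), seed = as.integer(seed))
}

# Build a DecisionTree from a raw node table (used by crossover and IO).
newTreeFromNodes <- function(nodes, featurePool, nFeatures, seed = 0L) {
  new("DecisionTree", nodes = nodes,
      featurePool = as.integer(sort(unique(featurePool))),
      nFeatures = as.integer(nFeatures), seed = as.integer(seed))
}

#' @describeIn trainTree depth of a tree (root = depth 0; a single leaf has
#'   depth 0).
#' @param x a DecisionTree.
#' @param ... unused.
#' @export
setMethod("treeDepth", "DecisionTree", function(x, ...) {
  max(nodeDepths(x@nodes))
})

# depth of every node, root = 0
nodeDepths <- function(nodes) {
  d <- rep(NA_integer_, nrow(nodes))
  d[1] <- 0L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (id in frontier) {
      if (nodes[id, "feature"] != 0) {
        ch <- c(nodes[id, "left"], nodes[id, "right"])
        d[ch] <- d[id] + 1L
        nxt <- c(nxt, ch)
      }
    }
    frontier <- nxt
  }
  d
}

setMethod("show", "DecisionTree", function(object) {
  internal <- sum(object@nodes[, "feature"] != 0)
  cat("DecisionTree:", internal, "splits,", nrow(object@nodes) - internal,
      "leaves, depth", treeDepth(object), "\n")
})

#' Predict class labels with a tree or forest
#'
#' Trees route each sample from the root ("go left iff value <= threshold")
#' to a leaf; forests take the strict-majority vote over trees, with voting
#' ties resolved to +1 (HC).
#'
#' @param object a \linkS4class{DecisionTree} or \linkS4class{TreeForest}.
#' @param newdata numeric matrix of samples (rows) x voxels, or a
#'   \linkS4class{VoxelExperiment}.
#' @return numeric vector of predictions in \{-1, +1\}.
#' @export
setMethod("predict", "DecisionTree", function(object, newdata) {
  X <- asFeatureMatrix(newdata)
  if (ncol(X) != object@nFeatures)
    stop("sample dimensionality (", ncol(X), ") != tree's feature count (",
         object@nFeatures, ")")
  leaves <- cpp_route(object@nodes, X)
  unname(object@nodes[leaves, "label"])
})

asFeatureMatrix <- function(x) {
  if (is(x, "VoxelExperiment")) featureMatrix(x)
  else if (is.null(dim(x))) matrix(x, nrow = 1)
  else as.matrix(x)
}

#' Train a random forest of seeded CART trees
#'
#' `nTrees` trees are trained independently, each with its own child seed
#' derived from the forest seed, so the forest is fully deterministic.
#'
#' @inheritParams trainTree
#' @param nTrees number of trees (default 300).
#' @param seed forest seed; tree i uses `childSeed(seed, "tree", i)`.
#' @return a \linkS4class{TreeForest}.
#' @export
trainForest <- function(X, y, nTrees = 300L,
                        mFeatures = defaultMFeatures(ncol(X)),
                        sampleFraction = 1, seed = 0L, maxDepth = 20L,
                        minSamplesLeaf = 1L) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  X <- as.matrix(X)
  trees <- lapply(seq_len(nTrees), function(i)
    trainTree(X, y, mFeatures = mFeatures, sampleFraction = sampleFraction,
              seed = childSeed(seed, "tree", i), maxDepth = maxDepth,
              minSamplesLeaf = minSamplesLeaf))
  new("TreeForest", trees = trees, seed = as.integer(seed))
}

#' @describeIn trainForest number of trees in a forest.
#' @param x a TreeForest.
#' @export
setMethod("nTrees", "TreeForest", function(x, ...) length(x@trees))

#' @describeIn trainForest list of member \linkS4class{DecisionTree}s.
#' @export
setMethod("trees", "TreeForest", function(x, ...) x@trees)

setMethod("show", "TreeForest", function(object) {
  cat("TreeForest:", nTrees(object), "trees (seed", object@seed, ")\n")
})

#' @rdname predict-DecisionTree-method
#' @export
setMethod("predict", "TreeForest", function(object, newdata) {
  X <- asFeatureMatrix(newdata)
  P <- matrix(vapply(object@trees, function(tr) predict(tr, X),
                     numeric(nrow(X))), nrow = nrow(X))
  votes <- rowSums(P)
  ifelse(votes >= 0, 1, -1)  # tie -> +1
})

#' Evaluate a predictor's accuracy on a labelled set
#'
#' Accuracy is the number of correct predictions divided by the size of the
#' evaluation set.
#'
#' @param predictor a \linkS4class{DecisionTree}, \linkS4class{TreeForest},
#'   or an already-computed prediction vector.
#' @param X evaluation feature matrix (ignored when `predictor` is a
#'   vector).
#' @param y true labels in \{-1, +1\}.
#' @return an \linkS4class{EvaluationReport}.
#' @examples
#' evaluateAccuracy(c(1, 1, -1), y = c(1, -1, -1))
#' @export
evaluateAccuracy <- function(predictor, X = NULL, y) {
  if (length(y) == 0) stop("empty evaluation set")
  pred <- if (is.numeric(predictor)) predictor else predict(predictor, X)
  if (length(pred) != length(y)) stop("prediction/label length mismatch")
  nc <- sum(pred == y)
  new("EvaluationReport", accuracy = nc / length(y), nCorrect = as.integer(nc),
      nEval = length(y))
}

#' @describeIn evaluateAccuracy accuracy value of a report.
#' @param x an EvaluationReport.
#' @param ... unused.
#' @export
setMethod("accuracy", "EvaluationReport", function(x, ...) x@accuracy)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d/%d correct (accuracy %.4f)\n",
              object@nCorrect, object@nEval, object@accuracy))
})
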