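#' Voxel split-frequency ranking of a forest
#'
#' The frequency of a voxel is the number of internal nodes splitting on it,
#' summed over all trees (a voxel used twice in one tree counts twice);
#' with `countMode = "perTree"` each tree contributes at most 1 per voxel.
#' Voxels with frequency 0 are excluded; ties are broken by lower voxel
#' index.
#'
#' @param forest a \linkS4class{TreeForest}.
#' @param voxelIds optional identifiers for the feature columns; defaults
#'   to `v<index>`.
#' @param countMode "nodes" (default) or "perTree".
#' @return data.frame with columns `voxel_id`, `voxel_index`, `frequency`,
#'   sorted by descending frequency.
#' @export
voxelFrequencies <- function(forest, voxelIds = NULL,
                             countMode = c("nodes", "perTree")) {
  countMode <- match.arg(countMode)
  p <- forest@trees[[1]]@nFeatures
  if (is.null(voxelIds)) voxelIds <- paste0("v", seq_len(p))
  counts <- numeric(p)
  for (tr in trees(forest)) {
    used <- tr@nodes[tr@nodes[, "feature"] != 0, "feature"]
    if (countMode == "perTree") used <- unique(used)
    if (length(used)) {
      tab <- tabulate(used, nbins = p)
      counts <- counts + tab
    }
  }
  keep <- which(counts > 0)
  if (length(keep) == 0) {
    warning("forest contains only leaves; empty ranking")
    return(data.frame(voxel_id = character(0), voxel_index = integer(0),
                      frequency = integer(0)))
  }
  ord <- keep[order(-counts[keep], keep)]
  data.frame(voxel_id = voxelIds[ord], voxel_index = ord,
             frequency = as.integer(counts[ord]))
}

#' Subset-size sweep over the frequency ranking
#'
#' For each candidate size k in `seq(sizeRange[1], sizeRange[2], stride)`
#' (clipped to the ranking length), a plain random forest of
#' `evalForestSize` trees is trained on the training set restricted to the
#' top-k ranked voxels and scored on the validation set. The selected
#' subset is the smallest k attaining the peak validation accuracy; its
#' forest is also scored on the held-out test set.
#'
#' @param ranking data.frame from [voxelFrequencies()].
#' @param ds a \linkS4class{VoxelExperiment}.
#' @param split a \linkS4class{DataSplit}.
#' @param sizeRange two integers, the inclusive size interval (default
#'   c(70, 580)).
#' @param stride step between sizes (default 5).
#' @param evalForestSize trees in each evaluation forest (default 340).
#' @param seed seed for the evaluation forests.
#' @param maxDepth,minSamplesLeaf CART stopping parameters.
#' @return an \linkS4class{ImportanceResult} (with the abnormal-voxel
#'   fields still empty; see [abnormalVoxels()]).
#' @export
subsetSweep <- function(ranking, ds, split, sizeRange = c(70, 580),
                        stride = 5L, evalForestSize = 340L, seed = 0L,
                        maxDepth = 20L, minSamplesLeaf = 1L) {
  if (nrow(ranking) == 0) stop("empty ranking")
  if (sizeRange[2] > nrow(ranking) || sizeRange[1] > nrow(ranking)) {
    warning("size range clipped to ranking length (", nrow(ranking), ")")
    sizeRange <- pmin(sizeRange, nrow(ranking))
  }
  sizes <- unique(seq(max(1L, sizeRange[1]), sizeRange[2], by = stride))
  X <- featureMatrix(ds)
  y <- subjectLabels(ds)
  accs <- numeric(length(sizes))
  forests <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    cols <- ranking$voxel_index[seq_len(sizes[s])]
    f <- trainForest(X[split@train, cols, drop = FALSE], y[split@train],
                     nTrees = evalForestSize,
                     mFeatures = defaultMFeatures(length(cols)),
                     seed = childSeed(seed, "sweep", sizes[s]),
                     maxDepth = maxDepth, minSamplesLeaf = minSamplesLeaf)
    accs[s] <- accuracy(evaluateAccuracy(
      f, X[split@val, cols, drop = FALSE], y[split@val]))
    forests[[s]] <- f
  }
  best <- which.max(accs)  # ties -> smallest size
  cols <- ranking$voxel_index[seq_len(sizes[best])]
  testAcc <- accuracy(evaluateAccuracy(
    forests[[best]], X[split@test, cols, drop = FALSE], y[split@test]))
  new("ImportanceResult", ranking = ranking,
      subsetSizes = as.integer(sizes), subsetAccuracies = accs,
      selectedSize = as.integer(sizes[best]),
      selectedVoxels = ranking$voxel_id[seq_len(sizes[best])],
      testAccuracy = testAcc, nF = 0L, abnormalVoxels = character(0))
}

#' Extract the abnormal voxels from the selected subset
#'
#' Either the top `nF` voxels of the selected subset by frequency (ties:
#' lower voxel index, i.e. ranking order), or — in threshold mode — all
#' selected voxels whose frequency exceeds `freqThreshold`.
#'
#' @param x an \linkS4class{ImportanceResult}, or a ranking data.frame
#'   (then the whole ranking plays the role of the selected subset).
#' @param nF number of abnormal voxels to keep.
#' @param freqThreshold alternative to `nF`: keep voxels with
#'   frequency > freqThreshold.
#' @return for an ImportanceResult, an updated ImportanceResult; for a
#'   data.frame, the character vector of abnormal voxel ids.
#' @export
abnormalVoxels <- function(x, nF = NULL, freqThreshold = NULL) {
  if (is(x, "ImportanceResult")) {
    sel <- x@ranking[seq_len(x@selectedSize), , drop = FALSE]
    ids <- abnormalVoxels(sel, nF = nF, freqThreshold = freqThreshold)
    x@nF <- length(ids)
    x@abnormalVoxels <- ids
    validObject(x)
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!is.null(freqThreshold)) return(x$voxel_id[x$frequency > freqThreshold])
  if (is.null(nF) || nF <= 0) stop("nF must be a positive integer")
  if (nF > nrow(x)) stop("nF exceeds the selected subset size")
  x$voxel_id[seq_len(nF)]
}

#' @describeIn subsetSweep the frequency ranking of a result.
#' @param x an ImportanceResult.
#' @param ... unused.
#' @export
setMethod("ranking", "ImportanceResult", function(x, ...) x@ranking)

#' @describeIn subsetSweep voxel ids of the selected peak subset.
#' @export
setMethod("selectedVoxels", "ImportanceResult", function(x, ...) x@selectedVoxels)

#' @describeIn subsetSweep the abnormal voxel ids (after [abnormalVoxels()]).
#' @export
setMethod("abnormalVoxelSet", "ImportanceResult", function(x, ...) x@abnormalVoxels)

setMethod("show", "ImportanceResult", function(object) {
  cat("ImportanceResult:", nrow(object@ranking), "ranked voxels;",
      length(object@subsetSizes), "subset sizes swept\n")
  if (length(object@selectedSize))
    cat(sprintf("  selected size %d (val accuracy %.4f, test accuracy %.4f)\n",
                object@selectedSize, max(object@subsetAccuracies),
                object@testAccuracy))
  if (object@nF > 0)
    cat("  abnormal voxels: top", object@nF, "\n")
})

#' Overlap between two voxel sets
#'
#' @param setA,setB character vectors of voxel ids.
#' @return named numeric vector with `sizeA`, `sizeB` and `overlap`
#'   (the intersection cardinality), mirroring the discoveries/overlap
#'   layout used when comparing variant-selected voxel sets.
#' @export
overlapReport <- function(setA, setB) {
  c(sizeA = length(unique(setA)), sizeB = length(unique(setB)),
    overlap = length(intersect(setA, setB)))
}
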