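#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @export
setGeneric("subjectLabels", function(x, ...) standardGeneric("subjectLabels"))

#' @export
setGeneric("voxelIds", function(x, ...) standardGeneric("voxelIds"))

#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @export
setGeneric("nTrees", function(x, ...) standardGeneric("nTrees"))

#' @export
setGeneric("trees", function(x, ...) standardGeneric("trees"))

#' @export
setGeneric("treeDepth", function(x, ...) standardGeneric("treeDepth"))

#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @export
setGeneric("bestForest", function(x, ...) standardGeneric("bestForest"))

#' @export
setGeneric("bestGeneration", function(x, ...) standardGeneric("bestGeneration"))

#' @export
setGeneric("history", function(x, ...) standardGeneric("history"))

#' @export
setGeneric("maskCoords", function(x, ...) standardGeneric("maskCoords"))

#' @export
setGeneric("ranking", function(x, ...) standardGeneric("ranking"))

#' @export
setGeneric("selectedVoxels", function(x, ...) standardGeneric("selectedVoxels"))

#' @export
setGeneric("abnormalVoxelSet", function(x, ...) standardGeneric("abnormalVoxelSet"))
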