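#' Down-sample a 3-D volume by block-mean pooling
#'
#' Each output cell is the mean of its (at most `factor`^3) contributing
#' input cells; output extents are `ceiling(extent / factor)`, so edge
#' blocks are averaged over the available cells only. With factor 3 the
#' 182 x 218 x 182 template grid becomes 61 x 73 x 61. Block-mean pooling
#' preserves the intensity scale of VBM maps, and exactly conserves the
#' overall mean on divisible extents.
#'
#' @param volume 3-D numeric array (or an RNifti image; the result is a
#'   plain array, any `pixdim`/affine metadata is not rescaled).
#' @param factor positive integer down-sampling factor.
#' @return 3-D array of dimension `ceiling(dim(volume) / factor)`.
#' @examples
#' v <- array(1, dim = c(6, 6, 6))
#' dim(downsampleVolume(v, 3))
#' @export
downsampleVolume <- function(volume, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  d <- dim(volume)
  if (is.null(d) || length(d) != 3 || any(d == 0)) stop("volume must be a non-empty 3-D array")
  if (!all(is.finite(volume))) stop("volume intensities must be finite")
  if (factor == 1) return(array(as.numeric(volume), dim = d))
  x <- array(as.numeric(volume), dim = d)
  for (axis in 1:3) x <- poolAxis(x, factor, axis)
  x
}

# mean-pool one axis by `factor`, keeping partial edge blocks
poolAxis <- function(x, factor, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  d <- dim(xp)
  grp <- (seq_len(d[1]) - 1L) %/% factor + 1L
  m <- matrix(xp, nrow = d[1])
  pooled <- rowsum(m, grp, reorder = TRUE) / as.vector(table(grp))
  out <- array(pooled, dim = c(nrow(pooled), d[2], d[3]))
  aperm(out, order(perm))
}

#' Load a binary hippocampus mask from a NIfTI file
#'
#' Any nonzero cell counts as in-mask (label-valued atlas files are
#' tolerated). Coordinates are returned 1-based in lexicographic (i, j, k)
#' order with stable identifiers `<L|R>_i_j_k`, which fixes the voxel ->
#' feature-column map.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param gridShape expected 3-D grid extents (e.g. c(61, 73, 61)).
#' @param hemisphere "left" or "right".
#' @return a \linkS4class{VoxelMask}.
#' @export
loadVoxelMask <- function(path, gridShape, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  img <- RNifti::readNifti(path)
  maskFromArray(as.array(img), gridShape, hemisphere)
}

# mask construction from an in-memory array (shared by tests/synthetic IO)
maskFromArray <- function(arr, gridShape, hemisphere) {
  if (!identical(as.integer(dim(arr)), as.integer(gridShape)))
    stop("mask grid ", paste(dim(arr), collapse = "x"),
         " does not match expected grid ", paste(gridShape, collapse = "x"))
  nz <- which(arr != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("mask contains no nonzero cells")
  newVoxelMask(nz, hemisphere, gridShape)
}

#' @describeIn loadVoxelMask the ordered (i, j, k) coordinate matrix.
#' @param x a VoxelMask.
#' @param ... unused.
#' @export
setMethod("maskCoords", "VoxelMask", function(x, ...) x@coords)

#' @describeIn loadVoxelMask the stable voxel identifiers.
#' @export
setMethod("voxelIds", "VoxelMask", function(x, ...) x@voxelIds)

setMethod("show", "VoxelMask", function(object) {
  cat("VoxelMask (", object@hemisphere, "): ", nrow(object@coords),
      " voxels on a ", paste(object@gridShape, collapse = "x"), " grid\n",
      sep = "")
})

#' Extract per-subject voxel features from volumes through two masks
#'
#' One row per volume; columns are the left-mask voxels followed by the
#' right-mask voxels (the combined initial feature set), each cell the
#' intensity at that mask coordinate. Column order is fully determined by
#' the masks, so repeated calls give identical layouts.
#'
#' @param volumes list of 3-D arrays sharing the masks' grid shape.
#' @param left,right \linkS4class{VoxelMask} objects.
#' @param labels optional labels; when given, a
#'   \linkS4class{VoxelExperiment} is returned instead of a matrix.
#' @param subjectIds optional subject identifiers.
#' @return numeric matrix (n volumes x nLeft + nRight voxels) with the
#'   voxel ids as column names, or a VoxelExperiment when `labels` is
#'   supplied.
#' @export
extractVoxelFeatures <- function(volumes, left, right, labels = NULL,
                                 subjectIds = NULL) {
  if (!is.list(volumes)) volumes <- list(volumes)
  shape <- left@gridShape
  if (!identical(shape, right@gridShape))
    stop("left and right masks live on different grids")
  rows <- lapply(volumes, function(v) {
    if (!identical(as.integer(dim(v)), shape))
      stop("volume grid ", paste(dim(v), collapse = "x"),
           " does not match mask grid ", paste(shape, collapse = "x"))
    c(v[left@coords], v[right@coords])
  })
  X <- do.call(rbind, rows)
  colnames(X) <- c(left@voxelIds, right@voxelIds)
  if (!is.null(subjectIds)) rownames(X) <- subjectIds
  if (is.null(labels)) return(X)
  VoxelExperiment(X, labels, subjectIds = subjectIds)
}

#' Write a list of volumes and masks as NIfTI files
#'
#' @param volumes list of 3-D arrays.
#' @param left,right \linkS4class{VoxelMask} objects.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
writeNiftiFixtures <- function(volumes, left, right, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in seq_along(volumes)) {
    p <- file.path(dir, sprintf("subject%03d.nii.gz", s))
    RNifti::writeNifti(RNifti::asNifti(volumes[[s]]), p)
    paths <- c(paths, p)
  }
  for (m in list(left, right)) {
    arr <- array(0L, dim = m@gridShape)
    arr[m@coords] <- 1L
    p <- file.path(dir, paste0(m@hemisphere, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
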