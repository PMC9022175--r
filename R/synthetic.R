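#' Simulate a labelled subject-by-voxel dataset with planted signal
#'
#' Emulates the hippocampal voxel table: `nLeft` + `nRight` continuous
#' voxel features (defaults 281 + 302 = 583) for `nSubjects` subjects
#' (default 738, the AD + HC cohort size), with class balance
#' `classBalance` (default 442/738, the HC fraction). A seeded random
#' subset of `nInformative` voxels carries the signal: for those voxels
#' the class-conditional means are +effectSize/2 (HC, +1) and
#' -effectSize/2 (AD, -1) in units of `noiseSd`; all remaining voxels are
#' pure Gaussian noise. With `rho > 0`, voxels share a block-exchangeable
#' Gaussian component within each hemisphere, mimicking the spatial
#' correlation of smoothed VBM maps.
#'
#' @param nSubjects number of subjects (default 738).
#' @param nLeft,nRight voxels per hemisphere (defaults 281 and 302).
#' @param nInformative number of signal-carrying voxels.
#' @param effectSize class-mean separation in SD units.
#' @param noiseSd residual standard deviation.
#' @param classBalance fraction of +1 (HC) subjects.
#' @param rho within-hemisphere exchangeable correlation (default 0).
#' @param seed integer seed.
#' @return list with `dataset` (a \linkS4class{VoxelExperiment}),
#'   `informative` (ground-truth voxel ids) and `informativeIndex`
#'   (their column indices).
#' @examples
#' sim <- simulateVoxelData(nSubjects = 40, nLeft = 5, nRight = 5,
#'                          nInformative = 2, effectSize = 2, seed = 1)
#' sim$informative
#' @export
simulateVoxelData <- function(nSubjects = 738L, nLeft = 281L, nRight = 302L,
                              nInformative = 20L, effectSize = 1.5,
                              noiseSd = 1, classBalance = 442 / 738,
                              rho = 0, seed = 0L) {
  p <- nLeft + nRight
  if (nInformative > p) stop("nInformative exceeds the voxel count")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must be in (0, 1)")
  nPos <- round(classBalance * nSubjects)
  if (nPos < 1 || nPos > nSubjects - 1)
    stop("class balance leaves a class empty")
  voxIds <- c(sprintf("L%03d", seq_len(nLeft)), sprintf("R%03d", seq_len(nRight)))
  out <- withSeed(seed, {
    labels <- sample(c(rep(1, nPos), rep(-1, nSubjects - nPos)))
    info <- sort(sample.int(p, nInformative))
    X <- matrix(rnorm(nSubjects * p, sd = noiseSd), nSubjects, p)
    if (rho > 0) {  # block-exchangeable: shared hemisphere factor
      sf <- sqrt(rho) * noiseSd
      X <- X * sqrt(1 - rho)
      X[, seq_len(nLeft)] <- X[, seq_len(nLeft)] + rnorm(nSubjects, sd = sf)
      X[, nLeft + seq_len(nRight)] <-
        X[, nLeft + seq_len(nRight)] + rnorm(nSubjects, sd = sf)
    }
    X[, info] <- X[, info] + outer(labels, rep(effectSize * noiseSd / 2,
                                               nInformative))
    list(labels = labels, info = info, X = X)
  })
  ds <- VoxelExperiment(out$X, out$labels, voxelIds = voxIds,
                        subjectIds = sprintf("sub%04d", seq_len(nSubjects)))
  list(dataset = ds, informative = voxIds[out$info],
       informativeIndex = out$info)
}

#' Simulate NIfTI-shaped volumes and hemisphere masks matching a dataset
#'
#' Builds 3-D volumes on a `gridShape` grid (default 61 x 73 x 61, the
#' down-sampled image size) whose in-mask intensities reproduce
#' [simulateVoxelData()]'s feature matrix exactly — voxel column m of the
#' table equals the intensity at the m-th mask coordinate — enabling
#' end-to-end imaging-to-dataset round-trip tests. Mask coordinates are
#' compact blocks in the left (low-i) and right (high-i) halves of the
#' grid; off-mask cells are zero.
#'
#' @inheritParams simulateVoxelData
#' @param gridShape 3-D grid extents (default c(61, 73, 61)).
#' @return list with `volumes` (list of 3-D arrays), `leftMask` and
#'   `rightMask` (\linkS4class{VoxelMask}), plus the `dataset`,
#'   `informative` and `informativeIndex` of the matching
#'   [simulateVoxelData()] call.
#' @export
simulateVolumes <- function(nSubjects = 20L, nLeft = 281L, nRight = 302L,
                            nInformative = 20L, effectSize = 1.5,
                            noiseSd = 1, classBalance = 442 / 738, rho = 0,
                            seed = 0L, gridShape = c(61L, 73L, 61L)) {
  sim <- simulateVoxelData(nSubjects, nLeft, nRight, nInformative,
                           effectSize, noiseSd, classBalance, rho, seed)
  lcoords <- blockCoords(nLeft, iRange = c(5L, gridShape[1] %/% 2 - 2L),
                         gridShape = gridShape)
  rcoords <- blockCoords(nRight, iRange = c(gridShape[1] %/% 2 + 2L,
                                            gridShape[1] - 4L),
                         gridShape = gridShape)
  left <- newVoxelMask(lcoords, "left", gridShape)
  right <- newVoxelMask(rcoords, "right", gridShape)
  X <- featureMatrix(sim$dataset)
  volumes <- lapply(seq_len(nSubjects), function(s) {
    v <- array(0, dim = gridShape)
    v[left@coords] <- X[s, seq_len(nLeft)]
    v[right@coords] <- X[s, nLeft + seq_len(nRight)]
    v
  })
  c(list(volumes = volumes, leftMask = left, rightMask = right), sim)
}

# first n lexicographic (i,j,k) coordinates of a rectangular block
blockCoords <- function(n, iRange, gridShape) {
  js <- 10:(min(gridShape[2] - 5L, 40L))
  ks <- 10:(min(gridShape[3] - 5L, 40L))
  g <- expand.grid(k = ks, j = js, i = iRange[1]:iRange[2])
  g <- g[, c("i", "j", "k")]
  g <- g[order(g$i, g$j, g$k), ]
  if (n > nrow(g)) stop("block too small for requested mask size")
  as.matrix(g[seq_len(n), , drop = FALSE])
}

newVoxelMask <- function(coords, hemisphere, gridShape) {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("i", "j", "k"))
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  storage.mode(coords) <- "integer"
  ids <- sprintf("%s_%d_%d_%d", ifelse(hemisphere == "left", "L", "R"),
                 coords[, 1], coords[, 2], coords[, 3])
  new("VoxelMask", coords = coords, hemisphere = hemisphere,
      voxelIds = ids, gridShape = as.integer(gridShape))
}
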