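#' Construct a VoxelExperiment from a subject-by-voxel feature matrix
#'
#' @param features numeric matrix, one row per subject, one column per voxel.
#' @param labels numeric vector in \{-1, +1\} (AD = -1, HC = +1), or a
#'   character vector of group names to be passed through [encodeLabels()].
#' @param voxelIds,subjectIds optional identifier vectors; defaults are the
#'   matrix dimnames or \code{v1..vp} / \code{s1..sn}.
#' @return a \linkS4class{VoxelExperiment}.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' ve <- VoxelExperiment(x, rep(c(-1, 1), 5))
#' dim(featureMatrix(ve))
#' @export
VoxelExperiment <- function(features, labels, voxelIds = NULL,
                            subjectIds = NULL) {
  features <- as.matrix(features)
  if (is.character(labels)) labels <- encodeLabels(labels)
  if (length(labels) != nrow(features))
    stop("one label per subject (row) required")
  if (is.null(voxelIds))
    voxelIds <- colnames(features) %||% paste0("v", seq_len(ncol(features)))
  if (is.null(subjectIds))
    subjectIds <- rownames(features) %||% paste0("s", seq_len(nrow(features)))
  if (length(voxelIds) != ncol(features))
    stop("number of voxel ids must equal the column count")
  a <- t(features)
  dimnames(a) <- list(voxelIds, subjectIds)
  se <- SummarizedExperiment(
    assays = list(voxels = a),
    colData = DataFrame(label = as.numeric(labels), row.names = subjectIds))
  new("VoxelExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn VoxelExperiment subject-by-voxel feature matrix (transpose of
#'   the assay).
#' @param x a VoxelExperiment.
#' @param ... unused.
#' @export
setMethod("featureMatrix", "VoxelExperiment",
          function(x, ...) t(assay(x, "voxels")))

#' @describeIn VoxelExperiment numeric labels in \{-1, +1\}.
#' @export
setMethod("subjectLabels", "VoxelExperiment",
          function(x, ...) as.numeric(colData(x)$label))

#' @describeIn VoxelExperiment voxel identifiers (assay rownames).
#' @export
setMethod("voxelIds", "VoxelExperiment", function(x, ...) rownames(x))

#' @describeIn VoxelExperiment subject identifiers (assay colnames).
#' @export
setMethod("subjectIds", "VoxelExperiment", function(x, ...) colnames(x))

setMethod("show", "VoxelExperiment", function(object) {
  lab <- subjectLabels(object)
  cat("VoxelExperiment:", ncol(object), "subjects x", nrow(object),
      "voxels\n")
  cat("  AD (-1):", sum(lab == -1), "  HC (+1):", sum(lab == 1), "\n")
})

#' Encode diagnostic group names as numeric class labels
#'
#' AD is coded -1 and HC is coded +1 by default; groups without a mapping
#' entry (e.g. EMCI/LMCI under the default) raise an error, so mixed
#' cohort tables must be filtered to the mapped groups first.
#'
#' @param groups character vector of group names.
#' @param mapping named numeric vector from group name to label.
#' @return numeric vector in \{-1, +1\}, same length and order as `groups`.
#' @examples
#' encodeLabels(c("AD", "HC", "AD"))
#' @export
encodeLabels <- function(groups, mapping = c(AD = -1, HC = 1)) {
  if (length(groups) == 0) return(numeric(0))
  unknown <- setdiff(unique(groups), names(mapping))
  if (length(unknown))
    stop("no label mapping for group(s): ", paste(unknown, collapse = ", "))
  unname(mapping[groups])
}

#' Split subjects into train/validation/test sets by 6:2:2
#'
#' Sizes follow round(0.6 n) / round(0.2 n) with the remainder assigned to
#' the test set; the assignment is a seeded uniform permutation. The split
#' is not stratified; if any part misses a class a warning is raised.
#'
#' @param ds a \linkS4class{VoxelExperiment}, or an integer subject count.
#' @param ratios train/validation/test proportions, summing to 1.
#' @param seed integer seed.
#' @return a \linkS4class{DataSplit}.
#' @examples
#' splitDataset(10L, seed = 1)
#' @export
splitDataset <- function(ds, ratios = c(0.6, 0.2, 0.2), seed = 0L) {
  n <- if (is(ds, "VoxelExperiment")) ncol(ds) else as.integer(ds)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  if (n < 5) stop("need at least 5 subjects for a 6:2:2 split")
  n_train <- round(ratios[1] * n)
  n_val <- round(ratios[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produces an empty part; increase n")
  perm <- withSeed(seed, sample.int(n))
  sp <- new("DataSplit",
            train = sort(perm[seq_len(n_train)]),
            val = sort(perm[n_train + seq_len(n_val)]),
            test = sort(perm[n_train + n_val + seq_len(n_test)]),
            seed = as.integer(seed))
  if (is(ds, "VoxelExperiment")) {
    lab <- subjectLabels(ds)
    for (part in c("train", "val", "test"))
      if (length(unique(lab[slot(sp, part)])) < 2)
        warning("part '", part, "' does not contain both classes")
  }
  sp
}

setMethod("show", "DataSplit", function(object) {
  cat("DataSplit (seed ", object@seed, "): train ", length(object@train),
      " / val ", length(object@val), " / test ", length(object@test), "\n",
      sep = "")
})

#' Write / read a DataSplit as JSON
#'
#' @param split a \linkS4class{DataSplit}.
#' @param path file path.
#' @return `readSplit` returns a \linkS4class{DataSplit}.
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(
    list(seed = split@seed, train = split@train, val = split@val,
         test = split@test),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DataSplit", train = as.integer(x$train), val = as.integer(x$val),
      test = as.integer(x$test), seed = as.integer(x$seed))
}

#' Write / read the standard CSV feature table
#'
#' Column layout is `subject_id, <voxel ids...>, label`.
#'
#' @param ds a \linkS4class{VoxelExperiment}.
#' @param path file path.
#' @return `readVoxelTable` returns a \linkS4class{VoxelExperiment}.
#' @export
writeVoxelTable <- function(ds, path) {
  df <- data.frame(subject_id = subjectIds(ds),
                   featureMatrix(ds),
                   label = subjectLabels(ds),
                   check.names = FALSE)
  colnames(df) <- c("subject_id", voxelIds(ds), "label")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeVoxelTable
#' @export
readVoxelTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!identical(colnames(df)[1], "subject_id") ||
      !identical(colnames(df)[ncol(df)], "label"))
    stop("expected columns subject_id, <voxel ids...>, label")
  p <- ncol(df) - 2L
  x <- as.matrix(df[, 1L + seq_len(p), drop = FALSE])
  VoxelExperiment(x, df$label, voxelIds = colnames(df)[1L + seq_len(p)],
                  subjectIds = as.character(df$subject_id))
}
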