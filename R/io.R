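#' Serialize a forest to JSON and back
#'
#' Trees are written as nested node objects (`voxel`, `threshold`,
#' `left`, `right` for splits; `label` for leaves) together with each
#' tree's feature pool and seed; the round trip is lossless.
#'
#' @param forest a \linkS4class{TreeForest}.
#' @param path file path.
#' @return `readForest` returns the reconstructed
#'   \linkS4class{TreeForest}.
#' @export
writeForest <- function(forest, path) {
  treeToList <- function(nodes, id) {
    if (nodes[id, "feature"] == 0)
      list(label = nodes[id, "label"])
    else
      list(voxel = nodes[id, "feature"], threshold = nodes[id, "threshold"],
           left = treeToList(nodes, nodes[id, "left"]),
           right = treeToList(nodes, nodes[id, "right"]))
  }
  obj <- list(
    seed = forest@seed,
    nFeatures = forest@trees[[1]]@nFeatures,
    trees = lapply(trees(forest), function(tr)
      list(seed = tr@seed, featurePool = tr@featurePool,
           root = treeToList(tr@nodes, 1L))))
  # 17 significant digits guarantee bit-exact double round trips
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeForest
#' @export
readForest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- as.integer(obj$nFeatures)
  listToNodes <- function(root) {
    rows <- list()
    emit <- function(nd) {
      rows[[length(rows) + 1]] <<- c(0, NA, 0, 0, 0)
      self <- length(rows)
      if (!is.null(nd$label)) {
        rows[[self]][5] <<- as.numeric(nd$label)
      } else {
        l <- emit(nd$left)
        r <- emit(nd$right)
        rows[[self]] <<- c(as.numeric(nd$voxel), as.numeric(nd$threshold),
                           l, r, 0)
      }
      self
    }
    emit(root)
    m <- do.call(rbind, rows)
    colnames(m) <- c("feature", "threshold", "left", "right", "label")
    m
  }
  trees <- lapply(obj$trees, function(tr)
    newTreeFromNodes(listToNodes(tr$root),
                     as.integer(unlist(tr$featurePool)), p,
                     seed = as.integer(tr$seed)))
  new("TreeForest", trees = trees, seed = as.integer(obj$seed))
}

#' Serialize an EvolutionResult to JSON
#'
#' Writes variant, history, best generation, test accuracy, the config and
#' the best forest (nested as in [writeForest()]).
#'
#' @param result an \linkS4class{EvolutionResult}.
#' @param path file path.
#' @export
writeEvolutionResult <- function(result, path) {
  cfg <- result@config
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeForest(result@bestForest, tmp)
  jsonlite::write_json(list(
    variant = result@variant,
    bestGeneration = result@bestGeneration,
    history = result@history,
    testAccuracy = result@testAccuracy,
    config = list(nTrees = cfg@nTrees, generations = cfg@generations,
                  groupSize = cfg@groupSize,
                  offspringPerRound = cfg@offspringPerRound,
                  maxDepth = cfg@maxDepth, distanceOn = cfg@distanceOn,
                  seed = cfg@seed),
    bestForest = jsonlite::read_json(tmp, simplifyVector = FALSE)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
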