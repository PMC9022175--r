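#' Grid search over forest size and generations, with repeats
#'
#' For each forest size and each repeat, a single evolution run of
#' `maxGenerations` records the validation accuracy at every generation,
#' so the generations axis of the grid is read off one trajectory instead
#' of restarting per generation value (mathematically identical because
#' each generation's snapshot accuracy is recorded as the run proceeds).
#' The optimum is the (treeCount, generation) cell with maximal accuracy
#' over the best repeat; ties prefer fewer trees, then fewer generations.
#'
#' @param ds a \linkS4class{VoxelExperiment}.
#' @param split a \linkS4class{DataSplit}.
#' @param treeCounts forest sizes to try (default seq(300, 500, 20), 11
#'   sizes).
#' @param maxGenerations generations per run (default 500).
#' @param repeats independent repeats per size (default 10).
#' @param variant "cgrf" or "gerf" (evolutionary variants; for "rf" the
#'   generations axis collapses to 0).
#' @param seed root seed; repeat r of size t uses a child seed.
#' @param ... further arguments to [evolutionConfig()].
#' @return list with `best` (treeCount, generations, accuracy, repeat),
#'   `bestMean` (the cell maximising the mean over repeats), and `surface`
#'   (array sizes x generations+1 x repeats of validation accuracies).
#' @export
gridSearch <- function(ds, split, treeCounts = seq(300L, 500L, by = 20L),
                       maxGenerations = 500L, repeats = 10L,
                       variant = c("cgrf", "gerf", "rf"), seed = 0L, ...) {
  variant <- match.arg(variant)
  stopifnot(length(treeCounts) >= 1, !is.unsorted(treeCounts),
            maxGenerations >= 1, repeats >= 1)
  gens <- if (variant == "rf") 0L else as.integer(maxGenerations)
  surface <- array(NA_real_,
                   dim = c(length(treeCounts), gens + 1L, repeats),
                   dimnames = list(treeCounts, 0:gens, seq_len(repeats)))
  for (t in seq_along(treeCounts)) {
    for (r in seq_len(repeats)) {
      cfg <- evolutionConfig(nTrees = treeCounts[t], generations = gens,
                             seed = childSeed(seed, "grid",
                                              t * 100000L + r), ...)
      res <- runVariant(variant, ds, split, cfg)
      surface[t, , r] <- history(res)
    }
  }
  pickBest <- function(acc2d) {  # sizes x generations matrix
    best <- which(acc2d == max(acc2d), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    list(treeCount = treeCounts[best[1]], generations = best[2] - 1L,
         accuracy = acc2d[best[1], best[2]])
  }
  perRepeatMax <- apply(surface, 3, max)
  bestRep <- which.max(perRepeatMax)
  best <- pickBest(matrix(surface[, , bestRep], nrow = dim(surface)[1]))
  best$rep <- bestRep
  bestMean <- pickBest(apply(surface, c(1, 2), mean))
  list(best = best, bestMean = bestMean, surface = surface)
}

#' Write a tuning surface as long-format CSV
#'
#' Columns: tree_count, generation, repeat, val_accuracy.
#'
#' @param surface the array returned in `gridSearch()$surface`.
#' @param path file path.
#' @export
writeSurface <- function(surface, path) {
  d <- dimnames(surface)
  long <- expand.grid(tree_count = as.integer(d[[1]]),
                      generation = as.integer(d[[2]]),
                      rep = as.integer(d[[3]]))
  long$val_accuracy <- as.vector(surface)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
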