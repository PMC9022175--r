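#' Benchmark the four forest variants over repeated seeded runs
#'
#' Runs rf, gerf, cerf and cgrf on the same dataset and split for each of
#' `seeds` root seeds (the repeats differ in the randomly drawn features
#' and samples of the initial trees and in the evolution's randomness) and
#' tabulates the test accuracy of each run. Stability per variant is
#' reported as max - min accuracy across the repeats.
#'
#' @param ds a \linkS4class{VoxelExperiment}.
#' @param split a \linkS4class{DataSplit}.
#' @param config an \linkS4class{EvolutionConfig}; its seed slot is
#'   replaced per repeat.
#' @param seeds integer vector of root seeds (default 0:9, ten repeats).
#' @param variants subset of c("rf", "gerf", "cerf", "cgrf").
#' @param cerfGenerations iteration count used for cerf (its `generations`
#'   counts single-tree replacements, not rebuilds; default 20).
#' @return list with `accuracies` (data.frame variant / seed /
#'   test_accuracy / best_generation) and `stability` (named vector of
#'   max - min accuracy per variant).
#' @export
benchmarkVariants <- function(ds, split, config, seeds = 0:9,
                              variants = c("rf", "gerf", "cerf", "cgrf"),
                              cerfGenerations = 20L) {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      cfg <- config
      cfg@seed <- as.integer(s)
      if (v == "cerf") cfg@generations <- as.integer(cerfGenerations)
      res <- runVariant(v, ds, split, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, seed = s, test_accuracy = res@testAccuracy,
        best_generation = res@bestGeneration)
    }
  }
  acc <- do.call(rbind, rows)
  stability <- vapply(base::split(acc$test_accuracy, acc$variant),
                      function(a) max(a) - min(a), numeric(1))
  list(accuracies = acc, stability = stability[variants])
}
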