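#' Build an EvolutionConfig
#'
#' Bundles the parameters of a clustering genetic random forest run. One
#' generation rebuilds the whole population: `nTrees / offspringPerRound`
#' breeding rounds each contribute `offspringPerRound` retained offspring
#' (300 trees = 150 rounds of 2 by default).
#'
#' @param nTrees forest size (default 300).
#' @param generations number of generations to evolve (0 = plain forest).
#' @param groupSize trees per candidate group (default 5).
#' @param groupsPerRound disjoint groups drawn per round (default 2).
#' @param offspringPerRound offspring retained per round (default 2).
#' @param mFeatures features per tree; NA means floor(sqrt(p)) at fit time.
#' @param sampleFraction bootstrap fraction of training rows per tree.
#' @param maxDepth,minSamplesLeaf CART stopping parameters.
#' @param distanceOn space for the tree-distance metric: "predictions"
#'   (validation prediction vectors, the default) or "features" (0/1
#'   voxel-usage indicators).
#' @param seed root seed for the run.
#' @return an \linkS4class{EvolutionConfig}.
#' @export
evolutionConfig <- function(nTrees = 300L, generations = 10L, groupSize = 5L,
                            groupsPerRound = 2L, offspringPerRound = 2L,
                            mFeatures = NA_integer_, sampleFraction = 1,
                            maxDepth = 20L, minSamplesLeaf = 1L,
                            distanceOn = c("predictions", "features"),
                            seed = 0L) {
  new("EvolutionConfig", nTrees = as.integer(nTrees),
      generations = as.integer(generations), groupSize = as.integer(groupSize),
      groupsPerRound = as.integer(groupsPerRound),
      offspringPerRound = as.integer(offspringPerRound),
      mFeatures = as.integer(mFeatures), sampleFraction = sampleFraction,
      maxDepth = as.integer(maxDepth),
      minSamplesLeaf = as.integer(minSamplesLeaf),
      distanceOn = match.arg(distanceOn), seed = as.integer(seed))
}

setMethod("show", "EvolutionConfig", function(object) {
  cat("EvolutionConfig:", object@nTrees, "trees,", object@generations,
      "generations,", object@nTrees %/% object@offspringPerRound,
      "rounds/generation, distance on", object@distanceOn,
      paste0("(seed ", object@seed, ")\n"))
})

#' Prediction vector of a tree on an evaluation set
#'
#' The per-sample predictions of one tree, in \{-1, +1\}; this is the
#' vector the tree-distance metric operates on by default, so distance
#' between trees measures behavioural (classification) dissimilarity.
#'
#' @param tree a \linkS4class{DecisionTree}.
#' @param X evaluation matrix (e.g. the validation set features).
#' @return numeric vector of length nrow(X).
#' @export
predictionVector <- function(tree, X) {
  X <- asFeatureMatrix(X)
  if (nrow(X) == 0) stop("empty evaluation set")
  predict(tree, X)
}

# the vector a tree is embedded as, per the configured distance space
treeVector <- function(tree, valX, distanceOn = "predictions") {
  if (distanceOn == "predictions") predictionVector(tree, valX)
  else {
    v <- numeric(tree@nFeatures)
    used <- tree@nodes[tree@nodes[, "feature"] != 0, "feature"]
    v[unique(used)] <- 1
    v
  }
}

#' Euclidean distance between two tree vectors
#'
#' @param v1,v2 equal-length numeric vectors.
#' @return sqrt(sum((v1 - v2)^2)), a non-negative real.
#' @examples
#' treeDistance(c(0, 0), c(3, 4))  # 5
#' @export
treeDistance <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  sqrt(sum((v1 - v2)^2))
}

#' Upper-triangular similarity matrix of a candidate group
#'
#' Entry (i, j) for i < j is the Euclidean distance between the trees'
#' vectors; the diagonal and lower triangle are zero.
#'
#' @param group list of \linkS4class{DecisionTree} (length >= 2).
#' @param valX validation feature matrix.
#' @param distanceOn "predictions" or "features".
#' @param groupIndices optional population indices of the group members.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(group, valX, distanceOn = "predictions",
                             groupIndices = seq_along(group)) {
  g <- length(group)
  if (g < 2) stop("group must contain at least 2 trees")
  V <- vapply(group, treeVector, numeric(vectorLen(group[[1]], valX, distanceOn)),
              valX = valX, distanceOn = distanceOn)
  m <- matrix(0, g, g)
  for (i in seq_len(g - 1))
    for (j in (i + 1):g)
      m[i, j] <- treeDistance(V[, i], V[, j])
  new("SimilarityMatrix", entries = m, groupIndices = as.integer(groupIndices))
}

vectorLen <- function(tree, valX, distanceOn) {
  if (distanceOn == "predictions") nrow(asFeatureMatrix(valX)) else tree@nFeatures
}

setMethod("show", "SimilarityMatrix", function(object) {
  g <- nrow(object@entries)
  cat("SimilarityMatrix:", g, "trees,", g * (g - 1) / 2, "pairwise distances\n")
})

#' Clustering-based parent selection within a group
#'
#' Parent 1 is the tree with the best validation accuracy in the group;
#' parent 2 is the tree at the largest distance from parent 1 among the
#' remaining members — the two extremes of the group's similarity
#' structure, so a high-accuracy tree is paired with the tree most unlike
#' it. Ties go to the lowest group position.
#'
#' @param group list of \linkS4class{DecisionTree} (length >= 2).
#' @param valX,valY validation features and labels.
#' @param distanceOn "predictions" or "features".
#' @return list with elements `parent1`, `parent2` (group positions) and
#'   `accuracies`, `distances` (the quantities they maximise).
#' @export
selectParents <- function(group, valX, valY, distanceOn = "predictions") {
  if (length(group) < 2) stop("group must contain at least 2 trees")
  P <- vapply(group, function(tr) predictionVector(tr, valX),
              numeric(nrow(asFeatureMatrix(valX))))
  acc <- colMeans(P == valY)
  V <- if (distanceOn == "predictions") P else
    vapply(group, treeVector, numeric(group[[1]]@nFeatures),
           valX = valX, distanceOn = "features")
  selectParentsFromCache(acc, V)
}

# fast path shared with the engine: acc per member, V = member vectors
selectParentsFromCache <- function(acc, V) {
  p1 <- which.max(acc)  # ties -> lowest position
  d <- sqrt(colSums((V - V[, p1])^2))
  d[p1] <- -Inf
  p2 <- which.max(d)
  list(parent1 = p1, parent2 = p2, accuracies = acc,
       distances = replace(d, p1, 0))
}

#' Subtree crossover of two parent trees
#'
#' The offspring is a copy of `parentA` in which one uniformly chosen
#' internal node's subtree is replaced by a uniformly chosen subtree
#' (internal node or leaf) of `parentB`. If the result exceeds `maxDepth`,
#' every internal node at the cap depth is truncated to a leaf labelled by
#' the majority of the training rows routed to it (no routed rows or a
#' tie -> +1). The offspring's feature pool is the union of the parents'.
#'
#' @param parentA,parentB \linkS4class{DecisionTree} objects over the same
#'   feature space.
#' @param trainX,trainY training data used to relabel truncated nodes.
#' @param seed integer seed for the two node choices.
#' @param maxDepth depth cap applied to the offspring.
#' @param warnDegenerate warn when parentA is a single leaf (the breeding
#'   engine silences this expected degenerate case).
#' @return a \linkS4class{DecisionTree}.
#' @export
crossoverTrees <- function(parentA, parentB, trainX, trainY, seed = 0L,
                           maxDepth = 20L, warnDegenerate = TRUE) {
  stopifnot(parentA@nFeatures == parentB@nFeatures)
  An <- parentA@nodes
  internalA <- which(An[, "feature"] != 0)
  if (length(internalA) == 0) {
    if (warnDegenerate) warning("parentA is a single leaf; returning it unchanged")
    return(parentA)
  }
  pick <- withSeed(seed, c(internalA[sample.int(length(internalA), 1)],
                           sample.int(nrow(parentB@nodes), 1)))
  nodes <- spliceNodes(An, pick[1], parentB@nodes, pick[2])
  nodes <- truncateDepth(nodes, maxDepth, asFeatureMatrix(trainX), trainY)
  newTreeFromNodes(nodes, c(parentA@featurePool, parentB@featurePool),
                   parentA@nFeatures, seed)
}

# ids of the subtree rooted at `id` (including id)
subtreeIds <- function(nodes, id) {
  out <- integer(0)
  frontier <- id
  while (length(frontier)) {
    out <- c(out, frontier)
    kids <- c(nodes[frontier, "left"], nodes[frontier, "right"])
    frontier <- kids[kids != 0]
  }
  out
}

# replace the subtree at node a of A with the subtree at node b of B
spliceNodes <- function(An, a, Bn, b) {
  bsub <- sort(subtreeIds(Bn, b))
  Bpart <- Bn[bsub, , drop = FALSE]
  bmap <- integer(nrow(Bn))
  if (a == 1) {  # whole tree replaced
    bmap[bsub] <- seq_along(bsub)
    out <- Bpart
    nzl <- out[, "left"] != 0
    out[nzl, "left"] <- bmap[out[nzl, "left"]]
    nzr <- out[, "right"] != 0
    out[nzr, "right"] <- bmap[out[nzr, "right"]]
    rownames(out) <- NULL
    return(out)
  }
  drop <- subtreeIds(An, a)
  keep <- sort(setdiff(seq_len(nrow(An)), drop))
  amap <- integer(nrow(An))
  amap[keep] <- seq_along(keep)
  bmap[bsub] <- length(keep) + seq_along(bsub)
  Apart <- An[keep, , drop = FALSE]
  # remap A's child pointers; the edge into `a` now points at b's new id
  for (col in c("left", "right")) {
    ch <- Apart[, col]
    nz <- ch != 0
    ch[nz] <- ifelse(ch[nz] == a, bmap[b], amap[ch[nz]])
    Apart[, col] <- ch
  }
  for (col in c("left", "right")) {
    ch <- Bpart[, col]
    tgt <- ch != 0
    ch[tgt] <- bmap[ch[tgt]]
    Bpart[, col] <- ch
  }
  out <- rbind(Apart, Bpart)
  rownames(out) <- NULL
  out
}

# convert internal nodes at depth >= maxDepth to leaves; relabel them by
# majority of routed training rows (tie or none -> +1); drop unreachable rows
truncateDepth <- function(nodes, maxDepth, trainX, trainY) {
  d <- nodeDepths(nodes)
  over <- which(d >= maxDepth & nodes[, "feature"] != 0)
  if (length(over) == 0) return(nodes)
  nodes[over, "feature"] <- 0
  nodes[over, "threshold"] <- NA
  nodes[over, "left"] <- 0
  nodes[over, "right"] <- 0
  nodes[over, "label"] <- 0  # placeholder until relabelled
  reach <- sort(subtreeIds(nodes, 1L))
  map <- integer(nrow(nodes))
  map[reach] <- seq_along(reach)
  nodes <- nodes[reach, , drop = FALSE]
  for (col in c("left", "right")) {
    ch <- nodes[, col]
    nz <- ch != 0
    ch[nz] <- map[ch[nz]]
    nodes[, col] <- ch
  }
  rownames(nodes) <- NULL
  pending <- which(nodes[, "feature"] == 0 & nodes[, "label"] == 0)
  leaves <- cpp_route(nodes, trainX)
  for (id in pending) {
    yy <- trainY[leaves == id]
    nodes[id, "label"] <- if (sum(yy > 0) >= sum(yy < 0)) 1 else -1
  }
  nodes
}

#' One breeding round: two groups, four parents, four offspring, best two
#'
#' Two disjoint groups of `groupSize` trees are drawn from the population
#' without replacement; clustering-based selection yields parents (P1, P2)
#' and (P3, P4); the four cross-group pairings (P1,P3), (P1,P4), (P2,P3),
#' (P2,P4) each produce one offspring rooted in the first parent; the two
#' offspring with the highest validation accuracy are retained (ties:
#' pairing order).
#'
#' @param population list of \linkS4class{DecisionTree}.
#' @param trainX,trainY,valX,valY training and validation data.
#' @param seed round seed.
#' @param groupSize trees per group (default 5).
#' @param maxDepth offspring depth cap.
#' @param distanceOn "predictions" or "features".
#' @return list with `offspring` (the two retained trees), `parents`
#'   (population indices of P1..P4) and `candidateAccuracies`.
#' @export
breedingRound <- function(population, trainX, trainY, valX, valY, seed = 0L,
                          groupSize = 5L, maxDepth = 20L,
                          distanceOn = "predictions") {
  valX <- asFeatureMatrix(valX)
  cache <- buildCache(population, valX, valY, distanceOn)
  engineRound(population, cache, asFeatureMatrix(trainX), trainY, valX, valY,
              seed, groupSize, maxDepth, distanceOn)
}

buildCache <- function(trees, valX, valY, distanceOn) {
  P <- vapply(trees, function(tr) predict(tr, valX), numeric(nrow(valX)))
  V <- if (distanceOn == "predictions") P else
    vapply(trees, treeVector, numeric(trees[[1]]@nFeatures),
           valX = valX, distanceOn = "features")
  list(P = P, V = V, acc = colMeans(P == valY))
}

engineRound <- function(population, cache, trainX, trainY, valX, valY, seed,
                        groupSize, maxDepth, distanceOn,
                        parentRule = "cluster") {
  npop <- length(population)
  if (npop < 2 * groupSize)
    stop("population (", npop, ") too small for two disjoint groups of ",
         groupSize)
  idx <- withSeed(childSeed(seed, "groups"), sample.int(npop, 2 * groupSize))
  g1 <- idx[seq_len(groupSize)]
  g2 <- idx[groupSize + seq_len(groupSize)]
  pick <- function(g) {
    if (parentRule == "cluster") {
      s <- selectParentsFromCache(cache$acc[g], cache$V[, g, drop = FALSE])
      c(g[s$parent1], g[s$parent2])
    } else {  # "accuracy": top-2 accuracy, ties -> lowest position
      ord <- order(-cache$acc[g], seq_along(g))
      g[ord[1:2]]
    }
  }
  p12 <- pick(g1)
  p34 <- pick(g2)
  pairings <- list(c(p12[1], p34[1]), c(p12[1], p34[2]),
                   c(p12[2], p34[1]), c(p12[2], p34[2]))
  cand <- vector("list", 4)
  candP <- matrix(0, nrow(valX), 4)
  for (k in 1:4) {
    cand[[k]] <- crossoverTrees(population[[pairings[[k]][1]]],
                                population[[pairings[[k]][2]]],
                                trainX, trainY,
                                seed = childSeed(seed, "cross", k),
                                maxDepth = maxDepth, warnDegenerate = FALSE)
    candP[, k] <- predict(cand[[k]], valX)
  }
  accs <- colMeans(candP == valY)
  ord <- order(-accs, seq_len(4))  # ties -> pairing order
  keep <- ord[1:2]
  stopifnot(min(accs[keep]) >= max(accs[ord[3:4]]))
  list(offspring = cand[keep], offspringP = candP[, keep, drop = FALSE],
       offspringAcc = accs[keep], parents = c(p12, p34),
       candidateAccuracies = accs)
}

#' Rebuild the population by one generation of breeding rounds
#'
#' Runs `length(population) / offspringPerRound` breeding rounds, all
#' sampling groups from the incoming (old) population; the new population
#' is exactly the accumulated offspring — there is no elitist carry-over.
#'
#' @inheritParams breedingRound
#' @param offspringPerRound offspring retained per round (default 2).
#' @return list with `population` (the offspring list, same size as the
#'   input) and `roundLog` (one row per round).
#' @export
evolveGeneration <- function(population, trainX, trainY, valX, valY,
                             seed = 0L, groupSize = 5L,
                             offspringPerRound = 2L, maxDepth = 20L,
                             distanceOn = "predictions") {
  valX <- asFeatureMatrix(valX)
  cache <- buildCache(population, valX, valY, distanceOn)
  engineGeneration(population, cache, asFeatureMatrix(trainX), trainY, valX,
                   valY, seed, groupSize, offspringPerRound, maxDepth,
                   distanceOn)
}

engineGeneration <- function(population, cache, trainX, trainY, valX, valY,
                             seed, groupSize, offspringPerRound, maxDepth,
                             distanceOn, parentRule = "cluster",
                             generation = NA_integer_) {
  npop <- length(population)
  if (npop %% offspringPerRound != 0)
    stop("population size must be divisible by offspringPerRound")
  nrounds <- npop %/% offspringPerRound
  newpop <- vector("list", npop)
  newP <- matrix(0, nrow(valX), npop)
  newV <- NULL
  log <- vector("list", nrounds)
  for (r in seq_len(nrounds)) {
    res <- engineRound(population, cache, trainX, trainY, valX, valY,
                       childSeed(seed, "round", r), groupSize, maxDepth,
                       distanceOn, parentRule)
    at <- (r - 1L) * offspringPerRound + seq_len(offspringPerRound)
    newpop[at] <- res$offspring
    newP[, at] <- res$offspringP
    log[[r]] <- data.frame(generation = generation, round = r,
                           p1 = res$parents[1], p2 = res$parents[2],
                           p3 = res$parents[3], p4 = res$parents[4],
                           acc1 = res$candidateAccuracies[1],
                           acc2 = res$candidateAccuracies[2],
                           acc3 = res$candidateAccuracies[3],
                           acc4 = res$candidateAccuracies[4])
  }
  newV <- if (distanceOn == "predictions") newP else
    vapply(newpop, treeVector, numeric(newpop[[1]]@nFeatures),
           valX = valX, distanceOn = "features")
  list(population = newpop,
       cache = list(P = newP, V = newV, acc = colMeans(newP == valY)),
       roundLog = do.call(rbind, log))
}

ensembleAccuracy <- function(P, y) {
  votes <- rowSums(P)
  mean(ifelse(votes >= 0, 1, -1) == y)
}

#' Run the clustering genetic random forest
#'
#' Builds the initial forest (generation 0), evolves it for
#' `config@generations` generations, records the ensemble validation
#' accuracy of every generation, and returns the snapshot with the highest
#' validation accuracy (ties: earliest generation), evaluated on the
#' held-out test set.
#'
#' @param ds a \linkS4class{VoxelExperiment}.
#' @param split a \linkS4class{DataSplit} over the subjects of `ds`.
#' @param config an \linkS4class{EvolutionConfig}.
#' @return an \linkS4class{EvolutionResult}.
#' @examples
#' sim <- simulateVoxelData(nSubjects = 60, nLeft = 6, nRight = 6,
#'                          nInformative = 3, effectSize = 2, seed = 1)
#' sp <- splitDataset(sim$dataset, seed = 1)
#' cfg <- evolutionConfig(nTrees = 10, generations = 2, seed = 1)
#' res <- runEvolution(sim$dataset, sp, cfg)
#' history(res)
#' @export
runEvolution <- function(ds, split, config) {
  runVariant("cgrf", ds, split, config)
}

#' Run one of the four forest variants
#'
#' \describe{
#'   \item{rf}{the plain random forest (no evolution).}
#'   \item{gerf}{genetic evolution with accuracy-only parent selection:
#'     parents are the top-2 accuracy trees of each group.}
#'   \item{cerf}{clustering evolution without crossover: each iteration
#'     locates the most similar tree pair in the population (minimum
#'     distance), discards the pair's lower-accuracy member, and trains a
#'     fresh random tree in its place.}
#'   \item{cgrf}{the full clustering genetic random forest.}
#' }
#' For "cerf" the `generations` field counts replacement iterations rather
#' than population rebuilds.
#'
#' @param variant one of "rf", "gerf", "cerf", "cgrf".
#' @inheritParams runEvolution
#' @return an \linkS4class{EvolutionResult}.
#' @export
runVariant <- function(variant = c("cgrf", "rf", "gerf", "cerf"), ds, split,
                       config) {
  variant <- match.arg(variant)
  validObject(config)
  X <- featureMatrix(ds)
  y <- subjectLabels(ds)
  trainX <- X[split@train, , drop = FALSE]; trainY <- y[split@train]
  valX <- X[split@val, , drop = FALSE];     valY <- y[split@val]
  testX <- X[split@test, , drop = FALSE];   testY <- y[split@test]
  m <- if (is.na(config@mFeatures)) defaultMFeatures(ncol(X)) else config@mFeatures
  forest0 <- trainForest(trainX, trainY, nTrees = config@nTrees,
                         mFeatures = m, sampleFraction = config@sampleFraction,
                         seed = childSeed(config@seed, "init-forest"),
                         maxDepth = config@maxDepth,
                         minSamplesLeaf = config@minSamplesLeaf)
  population <- trees(forest0)
  cache <- buildCache(population, valX, valY, config@distanceOn)
  history <- ensembleAccuracy(cache$P, valY)
  best <- list(pop = population, gen = 0L, acc = history[1])
  logs <- list()
  gens <- if (variant == "rf") 0L else config@generations
  for (g in seq_len(gens)) {
    gseed <- childSeed(config@seed, "generation", g)
    if (variant == "cerf") {
      step <- cerfIteration(population, cache, trainX, trainY, valX, valY,
                            gseed, m, config)
    } else {
      step <- engineGeneration(population, cache, trainX, trainY, valX, valY,
                               gseed, config@groupSize,
                               config@offspringPerRound, config@maxDepth,
                               config@distanceOn,
                               parentRule = if (variant == "gerf") "accuracy"
                                            else "cluster",
                               generation = g)
      logs[[g]] <- step$roundLog
    }
    population <- step$population
    cache <- step$cache
    history <- c(history, ensembleAccuracy(cache$P, valY))
    if (history[g + 1] > best$acc)
      best <- list(pop = population, gen = g, acc = history[g + 1])
  }
  bestForest <- new("TreeForest", trees = best$pop, seed = config@seed)
  new("EvolutionResult", bestForest = bestForest,
      bestGeneration = best$gen, history = history,
      testAccuracy = mean(predict(bestForest, testX) == testY),
      variant = variant, config = config,
      roundLog = if (length(logs)) do.call(rbind, logs) else data.frame())
}

# one clustering-evolution iteration: drop one member of the most similar
# pair (the lower-accuracy one), refill with a fresh random tree
cerfIteration <- function(population, cache, trainX, trainY, valX, valY,
                          seed, mFeatures, config) {
  D <- as.matrix(stats::dist(t(cache$V)))
  D[lower.tri(D, diag = TRUE)] <- Inf
  ij <- arrayInd(which.min(D), dim(D))  # ties -> lexicographically first
  i <- ij[1]; j <- ij[2]
  drop <- if (cache$acc[i] <= cache$acc[j]) {
    if (cache$acc[i] == cache$acc[j]) j else i  # tie -> keep earlier tree
  } else j
  fresh <- trainTree(trainX, trainY, mFeatures = mFeatures,
                     sampleFraction = config@sampleFraction,
                     seed = childSeed(seed, "refill"),
                     maxDepth = config@maxDepth,
                     minSamplesLeaf = config@minSamplesLeaf)
  population[[drop]] <- fresh
  cache$P[, drop] <- predict(fresh, valX)
  cache$V[, drop] <- treeVector(fresh, valX, config@distanceOn)
  cache$acc[drop] <- mean(cache$P[, drop] == valY)
  list(population = population, cache = cache)
}

#' @describeIn runVariant best forest snapshot of a result.
#' @param x an EvolutionResult.
#' @param ... unused.
#' @export
setMethod("bestForest", "EvolutionResult", function(x, ...) x@bestForest)

#' @describeIn runVariant generation index of the best snapshot.
#' @export
setMethod("bestGeneration", "EvolutionResult", function(x, ...) x@bestGeneration)

#' @describeIn runVariant per-generation validation accuracies (generation
#'   0 first).
#' @export
setMethod("history", "EvolutionResult", function(x, ...) x@history)

#' @describeIn runVariant test-set accuracy of the best snapshot.
#' @export
setMethod("accuracy", "EvolutionResult", function(x, ...) x@testAccuracy)

setMethod("show", "EvolutionResult", function(object) {
  cat(sprintf(paste0("EvolutionResult (%s): best generation %d of %d, ",
                     "val accuracy %.4f, test accuracy %.4f\n"),
              object@variant, object@bestGeneration,
              length(object@history) - 1L, max(object@history),
              object@testAccuracy))
})
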