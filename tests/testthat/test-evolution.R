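test_that("prediction vectors match per-sample tree calls", {
  d <- makeToyData(30, 4, seed = 2)
  tr <- trainTree(d$X, d$y, mFeatures = 3L, seed = 3)
  v <- predictionVector(tr, d$X)
  expect_equal(v, sapply(seq_len(30), function(r) predict(tr, d$X[r, , drop = FALSE])))
  expect_equal(predictionVector(leafTree(1), matrix(0, 4, 4)), rep(1, 4))
  expect_error(predictionVector(tr, d$X[0, , drop = FALSE]), "empty")
})

test_that("tree distance is the Euclidean norm with the 2*sqrt(k) identity", {
  expect_equal(treeDistance(c(1, -1, 1), c(1, -1, 1)), 0)
  expect_equal(treeDistance(c(0, 0), c(3, 4)), 5)
  for (k in c(1, 4, 9)) {
    v1 <- rep(1, 20)
    v2 <- v1; v2[seq_len(k)] <- -1
    expect_equal(treeDistance(v1, v2), 2 * sqrt(k))
    # direct summation oracle
    expect_equal(treeDistance(v1, v2), sqrt(sum((v1 - v2)^2)))
  }
  expect_error(treeDistance(1:3, 1:4), "equal length")
})

test_that("the distance is a metric on +/-1 prediction vectors", {
  set.seed(21)
  for (i in 1:20) {
    a <- sample(c(-1, 1), 15, TRUE)
    b <- sample(c(-1, 1), 15, TRUE)
    c_ <- sample(c(-1, 1), 15, TRUE)
    expect_equal(treeDistance(a, b), treeDistance(b, a))
    expect_equal(treeDistance(a, a), 0)
    expect_lte(treeDistance(a, c_),
               treeDistance(a, b) + treeDistance(b, c_) + 1e-12)
  }
})

test_that("similarity matrices are strictly upper-triangular distance tables", {
  d <- makeToyData(40, 5, seed = 4)
  grp <- lapply(1:5, function(i) trainTree(d$X, d$y, mFeatures = 2L, seed = i))
  sm <- similarityMatrix(grp, d$X)
  e <- sm@entries
  expect_identical(dim(e), c(5L, 5L))
  expect_true(all(e[lower.tri(e, diag = TRUE)] == 0))
  expect_equal(sum(upper.tri(e)), 10)  # M_{1,2}..M_{4,5}
  # O(g^2) double-loop oracle
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(e[i, j], sqrt(sum((predictionVector(grp[[i]], d$X) -
                                    predictionVector(grp[[j]], d$X))^2)))
  same <- replicate(5, leafTree(1, p = 5), simplify = FALSE)
  expect_true(all(similarityMatrix(same, d$X)@entries == 0))
  expect_error(similarityMatrix(grp[1], d$X), "at least 2")
})

test_that("parent selection picks the accuracy and distance extremes", {
  d <- makeToyData(40, 5, seed = 5)
  val <- makeToyData(24, 5, seed = 6)
  grp <- lapply(1:5, function(i) trainTree(d$X, d$y, mFeatures = 3L, seed = i))
  sel <- selectParents(grp, val$X, val$y)
  # brute-force enumeration oracle over the whole group
  accs <- sapply(grp, function(tr) mean(predict(tr, val$X) == val$y))
  p1 <- which(accs == max(accs))[1]
  dists <- sapply(grp, function(tr)
    treeDistance(predictionVector(tr, val$X), predictionVector(grp[[p1]], val$X)))
  dists[p1] <- -Inf
  expect_equal(sel$parent1, p1)
  expect_equal(sel$parent2, which(dists == max(dists))[1])
  # all-identical group: tie rule gives first non-parent1 position
  same <- replicate(5, leafTree(1, p = 5), simplify = FALSE)
  sel2 <- selectParents(same, val$X, val$y)
  expect_equal(sel2$parent1, 1)
  expect_equal(sel2$parent2, 2)
})

test_that("crossover splices a parentB subtree into parentA", {
  d <- makeToyData(50, 4, seed = 7)
  # depth-1 parents: offspring predictions must equal quadrant enumeration
  a <- stumpTree(1, 0.1, -1, 1)
  b <- stumpTree(2, -0.3, 1, -1)
  off <- crossoverTrees(a, b, d$X, d$y, seed = 11, maxDepth = 20)
  grid <- as.matrix(expand.grid(x1 = c(-1, 1.2), x2 = c(-1.3, 0.8),
                                x3 = 0, x4 = 0))
  ref <- sapply(seq_len(nrow(grid)), function(r)
    oraclePredictTree(nodesToNested(off@nodes), grid[r, ]))
  expect_equal(predict(off, grid), ref)
  expect_setequal(off@featurePool, union(a@featurePool, b@featurePool))
  # leaf-only parentA comes back unchanged with a warning
  expect_warning(out <- crossoverTrees(leafTree(1), b, d$X, d$y, seed = 1),
                 "single leaf")
  expect_identical(out@nodes, leafTree(1)@nodes)
})

test_that("crossover respects the depth cap via majority relabelling", {
  d <- makeToyData(80, 5, effect = 0.5, seed = 8)
  pa <- trainTree(d$X, d$y, mFeatures = 5L, seed = 1, maxDepth = 6L)
  pb <- trainTree(d$X, d$y, mFeatures = 5L, seed = 2, maxDepth = 6L)
  for (s in 1:10) {
    off <- crossoverTrees(pa, pb, d$X, d$y, seed = s, maxDepth = 6L)
    expect_lte(treeDepth(off), 6L)
    leaves <- off@nodes[off@nodes[, "feature"] == 0, "label"]
    expect_true(all(leaves %in% c(-1, 1)))
    expect_true(validObject(off))
  }
})

test_that("a breeding round keeps the best two of four cross-group offspring", {
  d <- makeToyData(60, 5, seed = 9)
  val <- makeToyData(30, 5, seed = 10)
  pop <- lapply(1:12, function(i) trainTree(d$X, d$y, mFeatures = 3L, seed = i))
  res <- breedingRound(pop, d$X, d$y, val$X, val$y, seed = 3)
  expect_length(res$candidateAccuracies, 4)
  expect_length(res$offspring, 2)
  # sort oracle: retained accuracies are the two largest candidate accuracies
  kept <- sapply(res$offspring, function(tr) mean(predict(tr, val$X) == val$y))
  expect_equal(sort(kept, decreasing = TRUE),
               sort(res$candidateAccuracies, decreasing = TRUE)[1:2])
  expect_error(breedingRound(pop[1:8], d$X, d$y, val$X, val$y, seed = 1),
               "too small")
})

test_that("a generation conserves population size with offspring only", {
  d <- makeToyData(60, 5, seed = 11)
  val <- makeToyData(30, 5, seed = 12)
  for (n in c(10L, 14L)) {
    pop <- lapply(seq_len(n), function(i)
      trainTree(d$X, d$y, mFeatures = 3L, seed = i))
    gen <- evolveGeneration(pop, d$X, d$y, val$X, val$y, seed = 5)
    expect_length(gen$population, n)
    expect_equal(nrow(gen$roundLog), n / 2)
  }
})

test_that("identical leaf populations pass through breeding unchanged", {
  d <- makeToyData(40, 4, seed = 13)
  val <- makeToyData(20, 4, seed = 14)
  pop <- replicate(10, leafTree(1), simplify = FALSE)
  res <- suppressWarnings(breedingRound(pop, d$X, d$y, val$X, val$y, seed = 1))
  for (off in res$offspring)
    expect_equal(predict(off, val$X), predict(pop[[1]], val$X))
  expect_equal(res$candidateAccuracies, rep(mean(val$y == 1), 4))
})

test_that("evolution runs are reproducible and track the best generation", {
  sim <- simulateVoxelData(nSubjects = 80, nLeft = 8, nRight = 8,
                           nInformative = 4, effectSize = 2, seed = 15)
  sp <- splitDataset(sim$dataset, seed = 15)
  cfg <- evolutionConfig(nTrees = 10L, generations = 4L, seed = 15)
  res <- runEvolution(sim$dataset, sp, cfg)
  expect_length(history(res), 5)
  expect_equal(history(res)[bestGeneration(res) + 1], max(history(res)))
  expect_gte(max(history(res)), history(res)[1])
  # byte-identical rerun, checked through lossless serialisation
  res2 <- runEvolution(sim$dataset, sp, cfg)
  p1 <- tempfile(); p2 <- tempfile()
  writeEvolutionResult(res, p1); writeEvolutionResult(res2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # generations = 0 returns the initial forest
  cfg0 <- evolutionConfig(nTrees = 10L, generations = 0L, seed = 15)
  res0 <- runEvolution(sim$dataset, sp, cfg0)
  f0 <- trainForest(featureMatrix(sim$dataset)[sp@train, ],
                    subjectLabels(sim$dataset)[sp@train], nTrees = 10L,
                    mFeatures = defaultMFeatures(16),
                    seed = childSeed(15L, "init-forest"))
  expect_identical(lapply(trees(bestForest(res0)), slot, "nodes"),
                   lapply(trees(f0), slot, "nodes"))
})

test_that("population size is conserved across many generations", {
  sim <- simulateVoxelData(nSubjects = 60, nLeft = 6, nRight = 6,
                           nInformative = 3, effectSize = 1.5, seed = 16)
  sp <- splitDataset(sim$dataset, seed = 16)
  cfg <- evolutionConfig(nTrees = 10L, generations = 20L, seed = 16)
  res <- suppressWarnings(runEvolution(sim$dataset, sp, cfg))
  expect_equal(nTrees(bestForest(res)), 10L)
  expect_length(history(res), 21)
  # every logged round retained offspring at least as good as discarded
  lg <- res@roundLog
  cand <- as.matrix(lg[, c("acc1", "acc2", "acc3", "acc4")])
  top2 <- t(apply(cand, 1, function(a) sort(a, decreasing = TRUE)[1:2]))
  expect_true(all(top2[, 2] >= apply(cand, 1, function(a)
    sort(a, decreasing = TRUE)[3])))
})

test_that("variants implement their selection and replacement rules", {
  sim <- simulateVoxelData(nSubjects = 80, nLeft = 8, nRight = 8,
                           nInformative = 4, effectSize = 2, seed = 17)
  sp <- splitDataset(sim$dataset, seed = 17)
  cfg <- evolutionConfig(nTrees = 10L, generations = 3L, seed = 17)
  rf <- runVariant("rf", sim$dataset, sp, cfg)
  expect_length(history(rf), 1)
  f0 <- trainForest(featureMatrix(sim$dataset)[sp@train, ],
                    subjectLabels(sim$dataset)[sp@train], nTrees = 10L,
                    mFeatures = defaultMFeatures(16),
                    seed = childSeed(17L, "init-forest"))
  expect_identical(lapply(trees(bestForest(rf)), slot, "nodes"),
                   lapply(trees(f0), slot, "nodes"))
  # cgrf is the same thing runEvolution computes
  expect_identical(
    history(runVariant("cgrf", sim$dataset, sp, cfg)),
    history(runEvolution(sim$dataset, sp, cfg)))
  # gerf: parents are the top-2 accuracy trees of each group (sort oracle)
  X <- featureMatrix(sim$dataset)
  y <- subjectLabels(sim$dataset)
  pop <- lapply(1:10, function(i) trainTree(X[sp@train, ], y[sp@train],
                                            mFeatures = 4L, seed = i))
  cache <- cgrf:::buildCache(pop, X[sp@val, ], y[sp@val], "predictions")
  rr <- cgrf:::engineRound(pop, cache, X[sp@train, ], y[sp@train],
                           X[sp@val, ], y[sp@val], 5L, 5L, 20L,
                           "predictions", parentRule = "accuracy")
  grp <- cgrf:::withSeed(childSeed(5L, "groups"), sample.int(10, 10))
  for (gi in list(grp[1:5], grp[6:10])) {
    top2 <- gi[order(-cache$acc[gi], seq_along(gi))][1:2]
    expect_true(all(top2 %in% rr$parents))
  }
  # cerf keeps the population size while replacing redundant trees
  cerf <- runVariant("cerf", sim$dataset, sp, cfg)
  expect_equal(nTrees(bestForest(cerf)), 10L)
  expect_length(history(cerf), 4)
})

test_that("cerf replaces the weaker member of the most similar pair", {
  d <- makeToyData(40, 4, seed = 18)
  val <- makeToyData(20, 4, seed = 19)
  pop <- lapply(1:6, function(i) trainTree(d$X, d$y, mFeatures = 3L, seed = i))
  cache <- cgrf:::buildCache(pop, val$X, val$y, "predictions")
  cfg <- evolutionConfig(nTrees = 6L, generations = 1L, groupSize = 3L,
                         seed = 1)
  out <- cgrf:::cerfIteration(pop, cache, d$X, d$y, val$X, val$y, 3L, 3L, cfg)
  changed <- which(sapply(1:6, function(i)
    !identical(out$population[[i]]@nodes, pop[[i]]@nodes)))
  expect_length(changed, 1)
  D <- as.matrix(dist(t(cache$P)))
  diag(D) <- Inf
  pair <- arrayInd(which.min(D), dim(D))
  expect_true(changed %in% pair)
  expect_lte(cache$acc[changed], max(cache$acc[pair]))
})
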