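test_that("voxel frequencies count internal-node occurrences", {
  # hand-built 2-tree forest: voxel 2 appears in 3 nodes, voxel 1 in 1
  n1 <- matrix(c(2, 0.0, 2, 3, 0,
                 2, -1.0, 4, 5, 0,
                 0, NA, 0, 0, 1,
                 0, NA, 0, 0, -1,
                 0, NA, 0, 0, 1), 5, 5, byrow = TRUE,
               dimnames = list(NULL, c("feature", "threshold", "left",
                                       "right", "label")))
  t1 <- cgrf:::newTreeFromNodes(n1, c(2L), 4L)
  t2 <- stumpTree(2, 0.5, -1, 1)
  t3 <- stumpTree(1, 0.5, -1, 1)
  f <- new("TreeForest", trees = list(t1, t2, t3), seed = 0L)
  r <- voxelFrequencies(f)
  expect_equal(r$voxel_index, c(2L, 1L))
  expect_equal(r$frequency, c(3L, 1L))
  # sum of frequencies equals the total internal node count
  expect_equal(sum(r$frequency),
               sum(sapply(trees(f), function(tr) sum(tr@nodes[, "feature"] != 0))))
  # per-tree presence counting collapses within-tree repeats
  rp <- voxelFrequencies(f, countMode = "perTree")
  expect_equal(rp$frequency[rp$voxel_index == 2], 2L)
  # leaf-only forests give an empty ranking with a warning
  fl <- new("TreeForest", trees = list(leafTree(1)), seed = 0L)
  expect_warning(r0 <- voxelFrequencies(fl), "only leaves")
  expect_equal(nrow(r0), 0)
})

test_that("frequency ties break to the lower voxel index", {
  f <- new("TreeForest",
           trees = list(stumpTree(3, 0, -1, 1), stumpTree(1, 0, -1, 1)),
           seed = 0L)
  r <- voxelFrequencies(f)
  expect_equal(r$voxel_index, c(1L, 3L))
})

test_that("abnormal voxel extraction supports top-N and threshold modes", {
  rk <- data.frame(voxel_id = paste0("v", c(9, 2, 5, 7, 1)),
                   voxel_index = c(9L, 2L, 5L, 7L, 1L),
                   frequency = c(29L, 27L, 25L, 25L, 24L))
  expect_equal(abnormalVoxels(rk, nF = 3), c("v9", "v2", "v5"))
  expect_equal(abnormalVoxels(rk, nF = 5), rk$voxel_id)
  # threshold 24 keeps exactly the voxels with frequency >= 25
  expect_equal(abnormalVoxels(rk, freqThreshold = 24), rk$voxel_id[1:4])
  expect_equal(abnormalVoxels(rk, freqThreshold = 25), rk$voxel_id[1:2])
  expect_error(abnormalVoxels(rk, nF = 0), "positive")
  expect_error(abnormalVoxels(rk, nF = 9), "exceeds")
})

test_that("the sweep enumerates 103 subset sizes over (70, 580) by 5", {
  sim <- simulateVoxelData(nSubjects = 30, nInformative = 5,
                           effectSize = 2, seed = 20)
  sp <- splitDataset(sim$dataset, seed = 20)
  rk <- data.frame(voxel_id = voxelIds(sim$dataset),
                   voxel_index = seq_len(583),
                   frequency = rep(10L, 583))  # full-length ranking
  ir <- subsetSweep(rk, sim$dataset, sp, sizeRange = c(70, 580), stride = 5,
                    evalForestSize = 1L, maxDepth = 1L, seed = 20)
  expect_length(ir@subsetSizes, 103)
  expect_equal(ir@subsetSizes, seq(70L, 580L, by = 5L))
})

test_that("sweep selects a prefix at the validation peak and clips ranges", {
  sim <- simulateVoxelData(nSubjects = 150, nLeft = 15, nRight = 15,
                           nInformative = 6, effectSize = 3, seed = 21)
  sp <- splitDataset(sim$dataset, seed = 21)
  f <- trainForest(featureMatrix(sim$dataset)[sp@train, ],
                   subjectLabels(sim$dataset)[sp@train], nTrees = 40L,
                   seed = 21)
  rk <- voxelFrequencies(f, voxelIds(sim$dataset))
  expect_warning(
    ir <- subsetSweep(rk, sim$dataset, sp, sizeRange = c(70, 580), stride = 4,
                      evalForestSize = 30L, seed = 21),
    "clipped")
  expect_true(ir@selectedSize %in% ir@subsetSizes)
  expect_identical(ir@selectedVoxels, rk$voxel_id[seq_len(ir@selectedSize)])
  peak <- max(ir@subsetAccuracies)
  expect_equal(ir@subsetAccuracies[match(ir@selectedSize, ir@subsetSizes)], peak)
  # ties resolve to the smallest size
  expect_false(any(ir@subsetAccuracies[ir@subsetSizes < ir@selectedSize] >= peak))
  expect_error(subsetSweep(rk[0, ], sim$dataset, sp), "empty")
})

test_that("sweeping the full ranking matches a plain forest, same seed", {
  sim <- simulateVoxelData(nSubjects = 60, nLeft = 5, nRight = 5,
                           nInformative = 3, effectSize = 2, seed = 22)
  sp <- splitDataset(sim$dataset, seed = 22)
  f <- trainForest(featureMatrix(sim$dataset)[sp@train, ],
                   subjectLabels(sim$dataset)[sp@train], nTrees = 20L,
                   seed = 22)
  rk <- voxelFrequencies(f, voxelIds(sim$dataset))
  k <- nrow(rk)
  ir <- suppressWarnings(
    subsetSweep(rk, sim$dataset, sp, sizeRange = c(k, k), stride = 1,
                evalForestSize = 15L, seed = 7))
  cols <- rk$voxel_index
  ref <- trainForest(featureMatrix(sim$dataset)[sp@train, cols],
                     subjectLabels(sim$dataset)[sp@train], nTrees = 15L,
                     mFeatures = defaultMFeatures(k),
                     seed = childSeed(7L, "sweep", k))
  refAcc <- mean(predict(ref, featureMatrix(sim$dataset)[sp@val, cols]) ==
                 subjectLabels(sim$dataset)[sp@val])
  expect_equal(ir@subsetAccuracies[1], refAcc)
})

test_that("the sweep plateaus at the level of an informative-only oracle forest", {
  # at a large planted effect the peak subset classifies as well as a
  # forest trained on exactly the informative voxels, and so does the
  # full-ranking subset once every informative voxel is included
  sim <- simulateVoxelData(nSubjects = 300, nLeft = 50, nRight = 50,
                           nInformative = 10, effectSize = 3, seed = 23)
  sp <- splitDataset(sim$dataset, seed = 23)
  X <- featureMatrix(sim$dataset)
  y <- subjectLabels(sim$dataset)
  f <- trainForest(X[sp@train, ], y[sp@train], nTrees = 80L, seed = 23)
  rk <- voxelFrequencies(f, voxelIds(sim$dataset))
  ir <- suppressWarnings(
    subsetSweep(rk, sim$dataset, sp, sizeRange = c(10, 100), stride = 10,
                evalForestSize = 60L, seed = 23))
  oracleF <- trainForest(X[sp@train, sim$informativeIndex], y[sp@train],
                         nTrees = 60L, mFeatures = 3L, seed = 23)
  oracleAcc <- mean(predict(oracleF, X[sp@val, sim$informativeIndex]) ==
                    y[sp@val])
  expect_gte(max(ir@subsetAccuracies), oracleAcc - 0.05)
  covered <- ir@subsetSizes >= max(match(sim$informative, rk$voxel_id))
  expect_true(all(ir@subsetAccuracies[covered] >= oracleAcc - 0.05))
  amended <- abnormalVoxels(ir, nF = min(10L, ir@selectedSize))
  expect_equal(amended@nF, min(10L, ir@selectedSize))
  expect_true(all(amended@abnormalVoxels %in% ir@selectedVoxels))
})

test_that("overlap reports exact set cardinalities", {
  expect_equal(unname(overlapReport(c("a", "b"), c("c", "d"))), c(2, 2, 0))
  expect_equal(unname(overlapReport(c("a", "b"), c("a", "b", "c"))), c(2, 3, 2))
  set.seed(24)
  for (i in 1:5) {
    a <- sample(letters, 8)
    b <- sample(letters, 12)
    got <- overlapReport(a, b)
    expect_equal(unname(got["overlap"]), sum(a %in% b))
  }
})
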