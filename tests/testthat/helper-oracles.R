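# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package's C++/vectorised paths.

# Exhaustive CART reference: same rules as the implementation (Gini, midpoint
# thresholds, ties -> lower feature then lower threshold, majority leaves with
# ties -> +1), written as a plain recursive R function over ALL features in
# `pool`.
oracleGini <- function(y) {
  p <- mean(y == 1)
  1 - p^2 - (1 - p)^2
}

oracleBestSplit <- function(X, y, pool, minLeaf = 1) {
  best <- NULL
  for (f in sort(pool)) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (t in (v[-length(v)] + v[-1]) / 2) {
      l <- X[, f] <= t
      if (sum(l) < minLeaf || sum(!l) < minLeaf) next
      imp <- sum(l) * oracleGini(y[l]) + sum(!l) * oracleGini(y[!l])
      if (is.null(best) || imp < best$imp) best <- list(f = f, t = t, imp = imp)
    }
  }
  best
}

oracleTree <- function(X, y, pool, depth = 0, maxDepth = 20, minLeaf = 1) {
  leaf <- function() list(label = if (sum(y == 1) >= sum(y == -1)) 1 else -1)
  if (depth >= maxDepth || length(y) < 2 * minLeaf || length(unique(y)) < 2)
    return(leaf())
  s <- oracleBestSplit(X, y, pool, minLeaf)
  if (is.null(s)) return(leaf())
  l <- X[, s$f] <= s$t
  list(feature = s$f, threshold = s$t,
       left = oracleTree(X[l, , drop = FALSE], y[l], pool, depth + 1,
                         maxDepth, minLeaf),
       right = oracleTree(X[!l, , drop = FALSE], y[!l], pool, depth + 1,
                          maxDepth, minLeaf))
}

oraclePredictTree <- function(node, x) {
  while (is.null(node$label)) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$label
}

# convert a package node table to the oracle's nested form for comparison
nodesToNested <- function(nodes, id = 1) {
  if (nodes[id, "feature"] == 0)
    return(list(label = unname(nodes[id, "label"])))
  list(feature = unname(nodes[id, "feature"]),
       threshold = unname(nodes[id, "threshold"]),
       left = nodesToNested(nodes, nodes[id, "left"]),
       right = nodesToNested(nodes, nodes[id, "right"]))
}

# hand-assembled trees for prediction/frequency fixtures
leafTree <- function(label, p = 4) {
  nodes <- matrix(c(0, NA, 0, 0, label), 1, 5,
                  dimnames = list(NULL, c("feature", "threshold", "left",
                                          "right", "label")))
  cgrf:::newTreeFromNodes(nodes, integer(0), p)
}

stumpTree <- function(feature, threshold, leftLabel, rightLabel, p = 4) {
  nodes <- matrix(c(feature, threshold, 2, 3, 0,
                    0, NA, 0, 0, leftLabel,
                    0, NA, 0, 0, rightLabel),
                  3, 5, byrow = TRUE,
                  dimnames = list(NULL, c("feature", "threshold", "left",
                                          "right", "label")))
  cgrf:::newTreeFromNodes(nodes, feature, p)
}

# small labelled dataset with a planted signal on the first feature
makeToyData <- function(n = 60, p = 6, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + y * effect / 2
  list(X = X, y = y)
}
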