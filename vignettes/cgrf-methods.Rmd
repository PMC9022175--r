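---
title: "Clustering genetic random forests for voxel-based feature selection"
author: "cgrf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering genetic random forests for voxel-based feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural MRI studies of Alzheimer's disease (AD) often summarise the
hippocampus as a single region-of-interest volume, which hides spatially
localised atrophy. Working at the voxel level instead, each subject is
described by the intensities of a fixed set of hippocampal voxels (here
281 left-hemisphere plus 302 right-hemisphere voxels, 583 features in
total) from spatially normalised, smoothed, down-sampled T1 images, and
the question becomes: which voxels jointly discriminate AD patients
(label $-1$) from healthy controls (label $+1$), and how well?

`cgrf` implements an evolutionary ensemble classifier for this setting
and a frequency-based pipeline that turns the fitted ensemble into a
ranked "abnormal voxel" set.

## The model

### Base learners

Each base learner is a binary CART classification tree. For a dataset
with $p$ voxels, a tree draws one feature pool of
$m = \lfloor\sqrt{p}\rfloor$ voxels ($m = 24$ for $p = 583$) and a
bootstrap sample of the training rows (fraction 1.0, drawn with
replacement), then grows greedily by Gini-impurity minimisation:

* candidate thresholds are midpoints between consecutive distinct sorted
  values of a feature;
* the split minimising the weighted child impurity
  $n_L(1 - p_L^2 - q_L^2) + n_R(1 - p_R^2 - q_R^2)$ is chosen, with ties
  broken to the lower feature index and then the lower threshold, so the
  fit is fully deterministic given its seed;
* growth stops at node purity, at `minSamplesLeaf` (default 1), or at
  `maxDepth` (default 20); leaves take the majority label of their routed
  rows, ties going to $+1$.

A forest of `nTrees` such trees (default 300) predicts by strict majority
vote, voting ties again resolved to $+1$. Subjects are split
train/validation/test by 6:2:2 — sizes $\mathrm{round}(0.6n)$,
$\mathrm{round}(0.2n)$ and the remainder — with a seeded uniform
permutation and no stratification (a warning is raised if a part misses a
class).

### Evolution

The initial forest is generation 0 of a genetic program. One generation
rebuilds the population through `nTrees / 2` breeding rounds (150 rounds
for 300 trees), each of which:

1. draws two disjoint groups of five trees from the *old* population;
2. in each group, selects **parent 1** as the tree with the best
   validation accuracy and **parent 2** as the tree at the greatest
   Euclidean distance from parent 1 — the two extremes of the group's
   similarity structure, which is tabulated as a strictly
   upper-triangular matrix of pairwise distances;
3. forms four offspring from the four cross-group pairings
   $(P_1,P_3), (P_1,P_4), (P_2,P_3), (P_2,P_4)$, each offspring a copy of
   the first parent with one uniformly chosen internal node's subtree
   replaced by a uniformly chosen subtree of the second parent;
4. keeps the two offspring with the highest validation accuracy.

The new population is exactly the accumulated offspring; there is no
elitist carry-over within a generation, but the run returns the
generation *snapshot* with the highest ensemble validation accuracy
(earliest on ties), so the reported model can never be worse on the
validation set than the initial forest. Held-out test accuracy is
computed once, for that snapshot.

### What "distance between trees" means

The distance that drives parent selection needs a vector embedding of a
tree. The package defaults to the tree's vector of predictions on the
validation set (entries $\pm 1$), so distance measures *behavioural*
dissimilarity: two trees that classify every validation subject
identically are distance 0, and trees disagreeing on $k$ subjects are
$2\sqrt{k}$ apart. An alternative embedding — the 0/1 indicator of which
voxels the tree splits on — is available via
`evolutionConfig(distanceOn = "features")`. We measured both on synthetic
recovery problems while developing the package and kept the behavioural
embedding as the default: pairing an accurate tree with a behaviourally
different one gave equal or better held-out accuracy and planted-voxel
recovery than pairing by feature usage.

### Crossover details

Subtree exchange is the standard genetic-programming operator; the
donated subtree may be a single leaf. Two consequences need explicit
rules:

* **Depth**: a splice can exceed `maxDepth`. Every internal node at the
  cap depth is truncated to a leaf labelled by the majority of the
  training rows routed to it (no routed rows or a tie give $+1$).
* **Degenerate parents**: a single-leaf tree cannot receive a subtree;
  it is returned unchanged (with a warning when called directly).

The offspring's feature pool is the union of its parents' pools, so the
pool invariant (every split lies in the pool) is preserved.

### Baseline variants

For comparison, `runVariant()` provides:

* `rf` — the plain forest, no evolution;
* `gerf` — the same generational loop, but both parents of a group are
  chosen by accuracy alone (top 2);
* `cerf` — clustering without crossover: each iteration finds the most
  similar pair of trees in the whole population, discards the pair's
  lower-accuracy member, and trains a fresh random tree in its place;
  its `generations` parameter counts these replacement iterations;
* `cgrf` — the full method.

`benchmarkVariants()` repeats all four over a set of seeds and reports
per-variant accuracy and a stability figure (max − min accuracy across
repeats).

## Voxel importance

After evolution, the frequency of a voxel is the number of internal
nodes splitting on it, summed over the forest's trees; a voxel used
twice in one tree counts twice. Counting each tree at most once per
voxel is available via `countMode = "perTree"` — node counting is the
finer statistic and is the default. Voxels are ranked by descending
frequency (ties to the lower voxel index), and a subset-size sweep
trains a plain forest (default 340 trees) on the top-$k$ voxels for $k$
in an interval (default 70 to 580 by 5, clipped to the ranking length)
and scores it on the validation set. The selected subset is the smallest
$k$ attaining the peak validation accuracy — the parsimony tie rule —
and only that subset's forest is scored on the test set, keeping the
test set out of the selection loop. The sweep is scored on validation
rather than test for exactly that reason. Within the selected subset,
the top $N_f$ voxels by frequency (or all voxels above a frequency
threshold) are reported as the abnormal voxel set, and
`overlapReport()` compares sets selected by different variants.

## Parameter tuning

`gridSearch()` crosses forest sizes (default 300 to 500 by 20, eleven
values) with generation counts (default up to 500) over repeated runs
(default 10). Because every generation's snapshot accuracy is recorded
as a run proceeds, a single trajectory per (size, repeat) yields the
whole generations axis — mathematically identical to restarting per
generation value and vastly cheaper. The optimum is the cell with the
maximal accuracy over the best repeat (ties: fewer trees, then fewer
generations); the mean-over-repeats optimum is reported alongside.

## The synthetic generator

`simulateVoxelData()` emulates the cohort layout: 738 subjects by
default (442 labelled $+1$, 296 labelled $-1$), 281 + 302 = 583
continuous voxel features. A seeded random subset of `nInformative`
voxels carries the class signal — class-conditional means
$\pm\,\mathrm{effectSize}/2$ in units of `noiseSd` — and all other
voxels are independent Gaussian noise. An optional block-exchangeable
correlation (`rho`) adds a shared within-hemisphere factor, mimicking
the spatial smoothness of VBM maps. `simulateVolumes()` embeds the same
matrix into 61×73×61 grids behind compact left/right masks so the NIfTI
extraction path can be tested end to end: extraction of the simulated
volumes reproduces the feature matrix exactly.

What the generator does *not* emulate: realistic atrophy topography,
intensity non-Gaussianity, site effects, registration error, or
covariate structure (age, sex, education). Tests passing on this
generator therefore demonstrate correctness and internal consistency of
the algorithms, not clinical performance on real cohorts.

## Numerical and design choices

* **Down-sampling** is block-mean pooling with ceiling semantics at the
  edges: extents 182×218×182 become 61×73×61 at factor 3, partial edge
  blocks average over their available cells, and the overall mean is
  conserved on divisible extents. Mean pooling was chosen because it
  preserves the intensity scale of VBM maps; the choice of interpolant
  is ours.
* **Coordinates** are 1-based (R convention) and masks are ordered
  lexicographically by (i, j, k), which fixes the voxel-to-column map;
  any nonzero mask value counts as in-mask so label-valued atlas files
  load unchanged.
* **Seeding**: every source of randomness derives from one root seed
  through named substreams (`childSeed(seed, stream, index)`), so equal
  (data, config, seed) give byte-identical results, including the
  per-round log.
* **Ties** are always broken deterministically: lower feature index and
  threshold in splits, lowest group position in parent selection,
  pairing order among offspring, earliest generation among equal
  snapshots, smallest subset size at equal sweep accuracy, $+1$ in all
  label votes.
* **Serialisation** writes forests as nested JSON node objects with 17
  significant digits, which round-trips doubles bit-exactly.

## Known limitations

* Crossover can only recombine voxels already used by the current
  population: there is no mutation operator, so a voxel that drops out
  of every tree can never return. Over many generations the accuracy-
  greedy selection concentrates the population on fewer lineages, and
  the set of voxels the forest uses shrinks. When many voxels carry
  redundant signal, the evolved forest can reach its best accuracy
  while using — and therefore ranking — only part of the truly
  informative set. The frequency ranking should be read as "sufficient
  discriminative set", not as an exhaustive screen.
* The clustering step is the two-extreme selection described above, not
  a full clustering of the group; and the `cerf` baseline is a minimal
  redundancy-pruning-plus-refill reading of clustering-only evolution.
* Single-point subtree crossover with depth-cap truncation is one
  defensible operator among several; it was chosen as the standard
  genetic-programming operator consistent with recombining two tree
  parents.
* Whether the two five-tree groups may overlap is not fixed by the
  method's description; the package draws them disjoint, fresh each
  round, which keeps rounds independent.

## Scale of the shipped examples and tests

The package's tests and the `scripts/acceptance.R` protocol run the full
pipeline at a reduced scale chosen to keep a desktop run short while
preserving every structural property: 400 subjects, 583 voxels, 20
informative voxels at effect 1.5 SD, 100-tree forests evolved for 20
generations over ten (tests) or five (script) replicate seeds, with the
subset sweep at stride 15 and 100-tree evaluation forests. The
full-scale protocol (300-500 trees, hundreds of generations, stride-5
sweep with 340-tree forests) is available through the same functions and
the `exec/cgrf` command line.

```{r example}
library(cgrf)
sim <- simulateVoxelData(nSubjects = 400, nInformative = 20,
                         effectSize = 1.5, seed = 1)
sp  <- splitDataset(sim$dataset, seed = 1)
cfg <- evolutionConfig(nTrees = 100, generations = 20, seed = 1)
res <- runEvolution(sim$dataset, sp, cfg)
res
rk  <- voxelFrequencies(bestForest(res), voxelIds(sim$dataset))
ir  <- subsetSweep(rk, sim$dataset, sp, sizeRange = c(70, 580),
                   stride = 15, evalForestSize = 100, seed = 1)
ir
```
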