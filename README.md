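# cgrf — clustering genetic random forest for voxel-based feature selection

`cgrf` classifies subjects from voxel-level brain features — typically
hippocampal voxel intensities extracted from structural MRI — and ranks
the voxels that drive the classification. It is aimed at neuroimaging
studies that want to move below region-of-interest summaries: given a
subject × voxel table with labels coded AD = −1 / HC = +1, it fits an
evolutionary ensemble and reports a compact set of discriminative
("abnormal") voxels.

## The method

The base model is a random forest of CART trees: each tree draws
⌊√p⌋ features (24 of the 583 hippocampal voxels) and a bootstrap of the
training rows, grows by Gini minimisation, and the forest votes by
majority. Subjects are split train/validation/test by 6:2:2.

The forest is then evolved. Each generation rebuilds the population of
n trees through n/2 breeding rounds; a round

1. draws two disjoint groups of five trees,
2. selects in each group **parent 1** = the most accurate tree on the
   validation set and **parent 2** = the tree at the largest Euclidean
   distance from parent 1, where a tree is embedded as its ±1 prediction
   vector on the validation set and group distances form a strictly
   upper-triangular similarity matrix,
3. produces four offspring by subtree crossover of the cross-group
   pairings (P1,P3), (P1,P4), (P2,P3), (P2,P4),
4. retains the best two by validation accuracy.

The run returns the generation snapshot with the best ensemble
validation accuracy and scores it once on the held-out test set.
Variants `rf` (no evolution), `gerf` (accuracy-only parent selection)
and `cerf` (similarity pruning without crossover) are provided for
comparison, plus a grid search over (forest size, generations).

Voxel importance is split frequency: the number of internal nodes
splitting on a voxel, summed over the evolved forest. A subset-size
sweep retrains a plain forest on the top-k ranked voxels, picks the
smallest k at the peak validation accuracy, and the top-N_f voxels of
that subset (or all voxels above a frequency threshold) form the
abnormal voxel set.

See `vignettes/cgrf-methods.Rmd` for assumptions, tie rules, and
limitations.

## Worked example

A synthetic cohort with 20 planted informative voxels (effect 1.5 SD)
out of 583, the evolved forest, and the voxel-selection sweep:

```r
library(cgrf)
sim <- simulateVoxelData(nSubjects = 400, nInformative = 20,
                         effectSize = 1.5, seed = 4)
sp  <- splitDataset(sim$dataset, seed = 4)
sim$dataset
#> VoxelExperiment: 400 subjects x 583 voxels
#>   AD (-1): 160   HC (+1): 240
sp
#> DataSplit (seed 4): train 240 / val 80 / test 80

cfg <- evolutionConfig(nTrees = 100, generations = 20, seed = 4)
res <- runEvolution(sim$dataset, sp, cfg)
res
#> EvolutionResult (cgrf): best generation 4 of 20, val accuracy 0.9875, test accuracy 0.7875
```

Generation 0 is the plain forest (validation accuracy 0.8750 here);
evolution lifts the validation accuracy to 0.9875 by generation 4, and
that snapshot is the returned model. Voxel selection then runs on the
evolved forest:

```r
rk <- voxelFrequencies(bestForest(res), voxelIds(sim$dataset))
head(rk, 3)
#>   voxel_id voxel_index frequency
#> 1     L224         224       143
#> 2     R283         564       104
#> 3     L036          36        77

ir <- subsetSweep(rk, sim$dataset, sp, sizeRange = c(70, 580),
                  stride = 15, evalForestSize = 100, seed = 4)
ir
#> ImportanceResult: 103 ranked voxels; 3 subset sizes swept
#>   selected size 85 (val accuracy 0.9875, test accuracy 0.9625)

abnormalVoxelSet(abnormalVoxels(ir, nF = 20))
#>  [1] "L224" "R283" "L036" "R252" "R221" "R299" "R287" "L013" "R113" "L028"
#> [11] "L191" "R063" "L226" "R153" "L046" "L240" "R234" "R240" "R190" "L142"
```

The frequency ranking (143, 104, 77, … split occurrences) orders the
voxels the evolved forest relies on; the sweep finds that the top 85
voxels already reach the peak validation accuracy, and a plain forest on
that subset reaches 0.9625 test accuracy. The listed 20 voxels are the
highest-frequency members of the selected subset.

A command-line front end wraps the same pipeline
(`exec/cgrf simulate | extract-voxels | split | evolve | select-voxels |
tune | benchmark`).

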