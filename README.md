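# patchplex

Patch-based multiplex brain networks for two-group classification of
co-registered structural MRI.

## The problem

After a traumatic brain injury, some patients go on to develop epilepsy and
some do not, and the structural MRI changes that distinguish the two groups
are diffuse, multifocal and hard to segment: lesions, edema and deformation
defeat ROI pipelines. `patchplex` implements a segmentation-free
alternative: each co-registered, skull-stripped T1 volume is tiled into
homologous parallelepiped patches of `V` voxels (anchored at the medial
sagittal plane so the tiling covers both hemispheres uniformly), and every
patch pair is linked by the absolute Pearson correlation of their
voxel-wise intensities. Correlations below 0.3 are discarded as noise, and
patches that are more than 10% non-brain are excluded. Each subject thus
contributes one weighted network layer `G_α = (N, E, W)` over the shared
node set; the cohort of layers forms a multiplex network.

## The model

Per node `i` of layer `α`, with weights `w_ij ∈ {0} ∪ [0.3, 1]`:

- strength `s_i = Σ_j w_ij`;
- inverse participation ratio `y_i = Σ_j (w_ij / s_i)²`, whose reciprocal
  lies in `[1, k_i]` and measures how evenly the node's weight is spread
  over its `k_i` links;
- degree-conditional means `s(k)`, `Y(k)`: the averages of `s` and `y` over
  the `N_k` nodes of degree `k`;
- multiplex degree `k_multi_i = Σ_j a_multi_ij`, where `a_multi_ij = 1` when
  at least one layer links `i` and `j`;
- multiplex variants: `multiS_i = s_i · k_multi_i/(N−1)` and
  `multiY_i = y_i · k_multi_i/(N−1)`, plus conditional means over
  `k_multi` classes.

This yields `8N` features per subject (S, Y, Sc, Yc, multiS, multiY,
multiSc, multiYc). After removing constant and highly correlated (> 0.95)
columns, a repeated stratified cross-validation (default 1000 rounds,
balanced 80/20 splits) runs a nested 500-tree random forest on each round's
training part to select the features whose permutation importance exceeds
the third quartile, trains a second forest on those, and scores the
held-out part (accuracy, specificity, sensitivity, AUC; Wilson 95% interval
on the mean accuracy). Features selected more often than the chance rate
`p0 = 0.25` (one-sided proportion test, Bonferroni `α/N`) mark the patches
— and, via an optional anatomical label volume, the regions — that drive
the discrimination. A patch volume sweep (`V` = 1000..8000 by default)
shows at which spatial scales the group differences live.

The package also ships a synthetic phantom-cohort generator (shared smooth
template texture, per-subject noise, group effects planted in known
patches) so the whole pipeline can be exercised and validated without any
clinical data.

## Worked example

The reference phantom study: 30 subjects (15 + 15) of 40³ voxels under an
ellipsoid brain mask, with the texture of 3 known patches replaced by
independent fields ("decorrelated") in the case group.

```r
library(patchplex)

cohort <- phantom_cohort(effect_magnitude = 1, seed = 1)
cohort
#> <syn_cohort> 30 subjects (15 control / 15 case), volumes 40x40x40,
#>   3 planted patch(es), effect 'decorrelate' magnitude 1

config <- pipeline_config(scales = 512, rounds = 100, seed = 1)
result <- run_scale(cohort, 512, config)
result$grid
#> <patch_grid> 100 boxes of 8x8x8 voxels in a 40x40x40 volume; 28 valid nodes
result$cv
#> <cv_result> 100 rounds: accuracy 1.000 +/- 0.000
#>   (Wilson 95% CI [0.994, 1.000]), AUC 1.000 +/- 0.000

head(tidy(result$cv), 3)      # most stably selected features
#>   feature metric  node count frequency
#> 1 S_n053  S         53    80      0.8
#> 2 Y_n069  Y         69    78      0.78
#> 3 Sc_n072 Sc        72    78      0.78

cohort$truth %in% result$assessment$significant_nodes
#> [1] TRUE TRUE TRUE
```

The decorrelated patches disconnect from the rest of the network in case
subjects, so their strength/IPR features separate the groups perfectly
(accuracy 1.0 over 100 rounds), and all 3 planted patches are flagged by
the stability assessment. `autoplot(result$cv)`, `plot_metric_selection()`
and `autoplot()` of a `run_scale_sweep()` result give the standard figures.
A thin CLI over these functions lives in `inst/cli/patchplex.R`
(subcommands `simulate`, `grid`, `network`, `features`, `classify`,
`assess`, `sweep`).

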