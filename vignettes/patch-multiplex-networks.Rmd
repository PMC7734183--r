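---
title: "Patch-based multiplex brain networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based multiplex brain networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`patchplex` turns a cohort of co-registered, skull-stripped T1 volumes into
per-subject weighted brain networks, extracts nodal single-layer and
multiplex metrics at multiple patch scales, classifies two clinical groups
with repeated stratified cross-validation and nested random-forest feature
selection, and tests which patches are selected more often than chance.
This vignette documents the model, every tunable that matters, the
numerical conventions, the synthetic phantom the test suite runs on, and
the method's known limitations.

## From volumes to networks

The pipeline assumes its inputs already share one registered space;
`load_cohort()` enforces that contract (identical shape and voxel size) and
performs no registration, skull stripping or bias correction itself. The
brain mask, when not supplied, is the set of voxels positive in at least
half the subjects — appropriate for skull-stripped volumes whose
background is exactly zero.

**Patch grid.** The shared space is tiled into non-overlapping
parallelepipeds of `V` voxels. Because only `V` is specified by the method,
`choose_patch_shape()` picks the factorisation of `V` minimising the aspect
ratio (ties: lexicographically smallest triple): near-cubic patches sample
local texture as isotropically as possible. Tiling starts at the medial
sagittal plane `x = floor(Xdim/2)` and grows outward so both hemispheres
are covered by equal numbers of boxes (mirror-homologous for even `Xdim`);
on y and z it starts at voxel 0 — the x anchoring is dictated by the
hemispheric design, the y/z origin is our fixed convention. Incomplete
boundary boxes are dropped, since nodes must be equal-length intensity
vectors. A patch is a valid node only if its non-brain fraction does not
exceed 10% (*strictly*: exactly 10% non-brain is kept).

**Layers.** The link weight between two patches of one subject is the
absolute Pearson correlation of their voxelwise intensity vectors
(flattened x-fastest, identically for every subject); weights below 0.3
are set to zero — that threshold suppresses noise links while retaining
effective network structure, and `|r|` exactly 0.3 is kept ("lower than"
is strict). Two conventions the method leaves open are declared here: the
threshold applies to `|r|` (the weight *is* `|r|`), and a zero-variance
patch has no defined correlation, hence weight 0 rather than `NaN`.

**Multiplex.** All subjects' layers share the node set. The multiplex
degree `k_multi_i` counts the distinct partners of node `i` across the
union of layer edge sets (an edge present in every layer counts once).

## Nodal metrics and the 8N feature matrix

Per node and layer: strength `s_i = Σ_j w_ij`; inverse participation ratio
`y_i = Σ_j (w_ij/s_i)²` with `1/y_i ∈ [1, k_i]` (equal to `k_i` for
uniform weights, near 1 when one link dominates; `y_i = 0` by convention
for isolated nodes); and the degree-conditional means `s(k)`, `Y(k)` over
nodes sharing the degree. The conditional value is materialised per node,
which is what makes each conditional metric contribute `N` columns so the
total is `8N`.

The multiplex variants weigh the layer metrics on the multiplex degree.
The exact formula is not fixed by the method's description, so the package
declares one and isolates it in `multiplex_node_features()`:
`multiS_i = s_i · k_multi_i/(N−1)` and `multiY_i = y_i · k_multi_i/(N−1)`
(the normalised multiplex degree is used exactly once, the metrics reduce
to their single-layer versions on a complete multiplex and vanish for
multiplex-isolated nodes), while `multiSc`/`multiYc` condition on
`k_multi` classes instead of layer-degree classes. If a different
convention is ever preferred, only that one function changes.

**Filtering.** Before classification, constant (null mean and variance)
columns are removed, then pairs with Pearson correlation above 0.95 are
scanned in column order and the later column of each offending pair is
dropped, recording the retained partner. The scan is greedy against the
already-kept set, so the filter is idempotent and the first column of a
redundant group survives. Signed correlation is used, matching the
threshold's description; switching to `|r|` would be a one-line change.

## Classification and stability assessment

Each of the (default 1000) rounds: the majority class is undersampled
without replacement to the minority size — the stated intent is balanced
datasets — then each class is split 80/20 (counts rounded to nearest, at
least one validation subject per class). A 500-tree random forest with
`mtry = floor(sqrt(p))` is fit on the training rows only; features whose
out-of-bag permutation importance (mean decrease in accuracy) strictly
exceeds the third quartile of the importance distribution (linear
interpolation between order statistics) are selected; a second forest on
those features scores the held-out rows at the 0.5 probability cutoff,
with AUC from the predicted case probabilities. Selection and training
never see validation rows. Metrics are averaged over rounds; the mean
accuracy gets a Wilson 95% score interval with `n` equal to the pooled
validation classifications across rounds (the method does not state its
`n`; pooling is our declared choice). All round seeds derive from one
master seed, so a full run is bit-reproducible; forests run single-threaded
with fixed seeds for the same reason.

Each feature's selection count is then tested against the chance rate with
the one-sided test of equal or given proportions (chi-square with
continuity correction; an exact binomial test serves as the oracle in the
test suite), significant when `p < α/N` with `α = 0.05` and `N` the *node*
count — the Bonferroni divisor is N as the method states, although `8N`
features are tested; we implement it as written. The null proportion `p0`
is not stated by the method; we use `p0 = 0.25`, the marginal selection
rate the strict-Q3 rule induces (at most a quarter of features per round),
and it is configurable. Significant features map to their patches; with a
label volume, a region is reported for a patch when it occupies strictly
more than 10% of the patch's voxels.

One consequence of the correlation filter deserves its own paragraph.
Features of patches that carry the *same* information are collapsed to a
single representative column, so a patch whose features were all dropped
as duplicates can never be flagged directly, however informative it is.
`assess_features()` therefore (when given the filtered feature matrix)
extends the significant patch set through the recorded dropped-feature
partners: a patch whose feature was removed as a duplicate of a
significant retained feature is flagged as covered. Redundancy removal
then cannot silently discard an informative region.

## The synthetic phantom

`cohort_spec()`/`simulate_cohort()` generate desk-scale cohorts of
co-registered volumes; `phantom_cohort()` is the fixed reference study
(40³ voxels, ellipsoid mask, 8³ patches, 15+15 subjects, noise SD 0.5,
3 planted patches spread across the fully-brain part of the mask).

**Template.** Real T1 volumes show strong between-patch intensity
correlations (structural covariance); a plain smoothed-noise template does
not — distant patches would be uncorrelated textures, every network would
be empty at the 0.3 threshold, and nothing downstream could be tested. The
template therefore uses a *periodic* smooth texture (one seamless tile,
period equal to the patch dimensions, smoothed with a Gaussian kernel of
width 2 voxels) plus a low-amplitude (0.2 SD) large-scale field:
homologous patches share texture, within-subject patch correlations are
strong, and per-subject i.i.d. Gaussian noise (in template-SD units) tunes
them down realistically. Intensities are normalised to SD 1 inside the
mask and offset to be positive.

**Effects.** Case subjects receive one of two alterations inside the
planted patches, emulating localized post-injury intensity and texture
change. `mean_shift` adds `magnitude · SD` to the patch — note that a
constant offset leaves Pearson correlations unchanged, so this effect is
invisible to the network pipeline by construction (it exists to emulate
intensity alterations per se); `decorrelate` is the network-level effect:
the centred patch texture becomes
`sqrt(1−λ²)·texture + λ·independent_field` with `λ = min(magnitude, 1)`
and the field scaled to the patch SD — variance is matched exactly, the
correlation with the shared texture decays monotonically in the magnitude,
and `λ = 1` is full replacement. Magnitude 0 leaves volumes untouched, so
the null cohort is exchangeable between groups. Per-subject seeds derive
deterministically from the spec seed, independent of evaluation order.

**What the phantom does not model:** bias fields, motion, partial-volume
effects, anatomically shaped lesions, or registration error. Passing the
recovery tests shows the pipeline's machinery is correct and sensitive to
planted covariance changes at known locations; it does not certify
performance on clinical data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the reference phantom at
patch volume 512 with 100 CV rounds (28 valid nodes, ~30 s end to end),
and module tests use 18³–24³ toy cohorts; the configuration defaults
(scales 1000–8000, 1000 rounds) are the intended settings for real-size
volumes. Other numerical conventions collected in one place: validity and
region-overlap comparisons are strict inequalities on the 10% bounds (with
a 1e-12 guard on the brain fraction ratio); the Q3 cut is strict;
degenerate (all-equal) importance distributions fall back to the full
feature set with a warning; an empty grid, an all-dropped feature matrix,
or a class with too few subjects for a nonempty validation split raise
errors naming the offending quantity.

## Known limitations

- **The stability significance test is anti-conservative.** The proportion
  test treats a feature's selection count as Binomial(rounds, p0), i.e. it
  assumes rounds are independent. They are not: every round reuses the
  same subjects, so a feature that happens to look discriminative in the
  one realized dataset is selected in a large fraction of rounds. On null
  phantoms (no planted effect) the per-feature counts are strongly
  overdispersed — quantiles from 2 to 90 out of 100 rounds while the
  *marginal* rate is exactly 0.25 — and a nontrivial number of features
  passes the Bonferroni bar even though classification accuracy is at
  chance. Under round independence fewer than one false feature per run
  would be expected; the dependence inflates this by an order of
  magnitude. More rounds sharpen the test and make it worse. Significant
  features should therefore be read as "stably selected in this cohort",
  not as familywise-error-controlled discoveries; a permutation null
  (relabeling groups) would calibrate the counts properly and is the
  natural extension.
- The multiplex weighting formula is a declared convention (above), not a
  uniquely determined quantity.
- Balanced undersampling discards majority-class subjects each round;
  with strongly imbalanced cohorts the effective sample is the minority
  class size.
- The phantom's periodic texture makes all homologous patches mutually
  correlated — a stronger covariance structure than real anatomy; the
  planted-recovery results are a mechanism check, not an effect-size
  benchmark.
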