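---
title: "SpeckleQuant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpeckleQuant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpeckleQuant)
```

SpeckleQuant quantifies intranuclear foci (paraspeckles and similar bodies)
and nuclear protein accumulation in 3D confocal stacks, at the scale of
thousands of cells per condition. This vignette documents the model behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open.

## Data model

A `VoxelStack` is a (z, y, x, channel) intensity array with a physical voxel
size in micrometres and a role per channel: `nuclear` (DNA stain),
`cell_marker` (cell body / transfection marker, e.g. a GFP-IMPα fusion) and
`foci_marker` (the body marker being quantified, e.g. PSPC1, SFPQ or a
DsRed2 fusion). Confocal sampling is anisotropic — the z-step is typically
2–3× the xy pixel — so every distance and volume in the package is computed
in physical units; object volumes are voxel counts times the voxel volume
(μm³). Voxel indices are R's native 1-based indices throughout; the edge
test below therefore compares bounding boxes against 1 and the stack extent.

## Segmentation

The detection scheme is deliberately simple and fully open: intensity
thresholds, connected components and a seeded watershed. This replaces the
proprietary single-vendor "cells" modules used for this kind of analysis
with operators whose behaviour can be tested against ground truth.

* **Nuclei** (`detectNuclei`): voxels at or above `nucleusThreshold` are
  grouped by 26-connectivity (the most permissive standard connectivity —
  biased, intentionally, toward not missing nuclear material). Holes are
  filled per z-slice rather than in 3D: nucleolar voids must not fragment a
  nucleus, while 3D filling could bridge adjacent cells through the gap
  between slices. Components smaller than `minNucleusVolume` (default
  10 μm³, far below any real nucleus) are discarded. In practice the
  threshold is set generously low so that dim nuclei are still captured,
  accepting slight volume inflation; a threshold below background produces
  one component spanning most of the field, which is reported as a warning.
  With `splitTouchingNuclei = TRUE`, touching nuclei are separated by a
  watershed on the anisotropic Euclidean distance transform. Seeds are the
  connected cores where the distance reaches at least 60% of the
  component's maximum (and `seedMinDistance`, default 1 μm); this is robust
  to the plateaus a discretised anisotropic transform produces, where
  literal local maxima would over-seed.
* **Cells** (`detectCells`): the foreground is the union of voxels at or
  above the low `cellThreshold` — an auto-fluorescence-level gate, so every
  cell body is captured whether or not it is transfected — and all nucleus
  voxels. The foreground is partitioned among nuclei by a seeded watershed
  on inverted marker intensity, guaranteeing exactly one connected cell per
  nucleus; foreground unreachable from any nucleus is dropped. A cell whose
  region equals its nucleus is legal and flagged when ratios are computed.
* **Foci** (`detectFoci`): detection is restricted to nucleus voxels. In
  the default relative mode a voxel is a candidate when its foci-marker
  intensity is at least `focusMultiplier` (default 2) times the median
  foci-marker intensity of its own nucleus, which adapts to per-cell
  expression level; a nucleus with zero median falls back to the absolute
  threshold. Components smaller than `minFocusVolume` (default 0.04 μm³,
  two default voxels) are discarded. Raising a threshold can only shrink
  the candidate set, so focus counts are monotone non-increasing in the
  threshold — a property the tests enforce.
* **Linking** (`linkHierarchy`): each nucleus goes to the cell of maximal
  voxel overlap; each focus to the nucleus at its intensity-weighted
  centroid, falling back to maximal overlap when the centroid lands outside
  every nucleus (possible at nucleus borders in relative mode), with ties
  broken by overlap then lower label. A focus with no nucleus overlap at
  all is dropped and counted. Per-object voxel counts, volumes, bounding
  boxes and per-channel intensity sums are computed once here.

Thresholds are configuration, never auto-estimated — they are tuned per
experiment in practice — but `otsuThreshold()` is provided as an explicit
initialiser.

## Gating

Filters run in a fixed order, each logging its in/out counts so the chain
reconciles exactly:

1. **Edge nuclei**: a record is removed iff its *nucleus* bounding box
   touches the first or last plane along any configured axis (default all
   of x, y, z) — such nuclei are likely truncated and would bias volumes
   and foci counts.
2. **Orphan cells**: records with no linked nucleus are dropped
   (idempotent).
3. **Transfection gate**: only cells expressing the construct should enter
   group comparisons. The manual mode takes an explicit threshold on the
   per-cell mean cell-marker intensity. The calibrated mode
   operationalises "tune until the control count approaches zero" as a
   deterministic rule: the threshold is the empirical
   (1 − `controlPassFraction`) quantile (type 1, an order statistic) of the
   control cells, default pass fraction 1%. The gate keeps cells *strictly*
   above the threshold, so with pass fraction 0 an all-equal control sample
   excludes everything — the degenerate case is well defined. Controls can
   bypass the gate (`applyGateToControls = FALSE`) so that untransfected
   populations remain analysable with the same detection parameters.

## Per-cell and per-focus features

For each cell, with the cytoplasm defined as the 3D cell region minus its
nucleus:

$$F_{n/c} = \frac{\operatorname{mean}(I \mid \text{nucleus voxels})}
               {\operatorname{mean}(I \mid \text{cytoplasm voxels})}$$

Because both compartments are full 3D segments, bright substructure (foci in
the nucleus, aggregates in the cytoplasm) contributes to the means rather
than being sampled in or out by a mid-plane choice. Zero-cytoplasm cells
yield an undefined ratio and are flagged and excluded from F~n/c~ summaries
rather than raising an error. No background subtraction is applied before
the ratio (a config switch exists but defaults off), and intensities stay in
native detector units. Per-focus features are the voxel-count volume and the
mean/summed marker intensity; whether vendor tools report fitted-surface
rather than voxel volumes is unknowable from outside, so voxel-count volumes
are used and documented.

## Statistical layer

Three outcome types, following standard practice for this assay:

* **Binary** (cell foci-positive or not): Wald odds ratios against the
  reference group, CI $\exp(\ln OR \pm 1.959964\sqrt{\sum 1/n_{ij}})$,
  two-sided Wald p-values. A zero cell makes the OR non-estimable and is
  flagged; no continuity correction is applied by default because the
  intended use is large-n experiments where zero cells indicate a design
  problem.
* **Per-cell counts and continuous outcomes**: skewed, so analysed as
  natural-log linear models; exponentiating the group coefficients gives
  ratios of geometric means with exponentiated Wald intervals, and
  exponentiating a group's mean log gives its GM with a t-based CI
  (t with n−1 df is the standard small-sample default; at the cell counts
  this package targets the difference from a normal quantile is
  negligible). Count outcomes are analysed over foci-positive cells only by
  default (zero counts carry no information on the log scale); an
  `include_zeroes` mode using log(count + 1) is exposed for sensitivity
  analysis.
* **Per-focus outcomes**: foci from the same cell are correlated, so group
  ratios use generalized estimating equations: identity link on ln(value),
  exchangeable working correlation (the canonical choice when within-cell
  correlation has no further structure; independence is available), moment
  estimates of scale and correlation, and robust cluster-sandwich standard
  errors. The fitter exploits the closed-form inverse of the exchangeable
  covariance, so no per-cluster matrix inversion occurs. Three properties
  pin the implementation down in tests: with all-singleton clusters the
  estimates equal OLS to 10⁻⁸; duplicating balanced clusters leaves point
  estimates unchanged while shrinking the robust SE; and simulated
  clustered data with a known ratio and intraclass correlation are
  recovered within the robust CI.

Multiple testing uses the Bonferroni rule α / (number of experimental
groups) — the divisor convention of the group tables this layer mirrors
(0.05/6 reported as 0.008, 0.05/8 as 0.0063). `bonferroniThreshold()`
returns the exact quotient; reporting precision is applied at output time.

`intensityFncCorrelation()` pools cells across treatment groups and returns
the Pearson correlation (Spearman optional) between per-cell importin-marker
intensity and F~n/c~ — the population-level readout of transport activity.
`pcaGroupSummary()` condenses the groups × parameters matrix of geometric
means by covariance-mode (centred, unscaled) PCA: on raw parameter columns
whose magnitudes span orders of magnitude (intensity sums versus ratios) the
first component then concentrates almost all variance, which is the intended
"one axis separates the groups" summary; correlation-mode PCA is available
via `scale = TRUE` when columns should contribute equally.

## The synthetic generator

`generateStack()` emulates a single galvo-scanned confocal tile of adherent
HeLa-like cells; its defaults are the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| stack shape | 24 × 384 × 384 voxels | one tile, 12 × 77 × 77 μm |
| voxel size | 0.5 × 0.2 × 0.2 μm | typical 63× confocal sampling |
| cells per field | 20 | denser than typical tiles, still placeable |
| nucleus semi-axes | 2–3 μm in-plane, ×0.7 in z | flattened adherent nuclei |
| cytoplasm thickness | 0.8–1.6 μm | thin adherent shell |
| foci-positive probability π | 0.7 | mid-range of observed 28–91% |
| foci per positive cell | zero-truncated Poisson, λ = 8 | 5–20 foci typical |
| focus volumes | log-normal, GM 0.22 μm³, sdlog 0.5 | observed GMs 0.15–0.33 |
| F~n/c~ target | 2.69 | a reported full-length IMPα2 GM |
| focus contrast | 3× nucleoplasm (blob mean) | makes detection well-posed |
| noise, galvo | Poisson + Gaussian σ = 6 | high-quality slow scan |
| noise, resonance | 2× Poisson scaling, σ = 24 | 4× read noise, fast scan |

Foci are isotropic Gaussian blobs truncated at 2σ, with σ chosen so the 2σ
ball has the drawn volume, placed with a ≥0.5 μm surface gap inside the
nucleus (paraspeckles are discrete bodies; threshold detection of merged
blobs would be ill-posed). The blob amplitude makes the *mean* blob
intensity `fociContrast` times the nucleoplasm, and the nucleoplasm is then
lowered uniformly so that the whole-nucleus mean still realises the F~n/c~
target — the target refers to the compartment mean, foci included. The
galvo noise level was fixed so that the resonance regime (defined as 4× the
read noise and 2× the Poisson scaling) genuinely degrades foci detection —
reproducing the documented failure of fast resonance scanning for
sub-organelle features — while galvo-regime detection stays near-perfect;
this is a property of the regime pair, not a per-test adjustment.

Ground truth is voxel-level (label volumes for cells/nuclei/foci plus
per-cell true F~n/c~, foci counts and border flags), and identical
specifications reproduce bit-identical stacks. Detection quality is scored
by `matchObjects()`: greedy one-to-one matching by decreasing overlap,
accepting pairs with intersection-over-union ≥ 0.5 — the standard instance
criterion, under which both noise-inflated detections and components that
merge several true foci count as failures.

The generator does **not** emulate: an optical PSF (blobs are rendered, not
convolved), spectral bleed-through, tile stitching, uneven illumination,
mitotic or apoptotic morphologies, or textured chromatin. Passing tests on
synthetic fields therefore demonstrate the correctness of the operators and
the soundness of the thresholds' behaviour, not performance on any
particular real dataset; thresholds still need per-experiment tuning on real
images. One visible consequence of the generous gates is a small systematic
F~n/c~ overestimate on synthetic fields (about 4% at the defaults): the
low cell gate admits some background speckle into the cytoplasm, diluting
F~c~. The recovery tolerance in the tests (5%) was chosen to include this
known segmentation-level bias.

`generateCohort()` skips imaging entirely and draws the per-cell/per-focus
tables from the generative laws, with a per-cell random effect on log focus
volumes and intensities (inducing within-cell correlation for the GEE) and
an optional slope coupling marker intensity to F~n/c~ (setting the sign of
the marker–accumulation correlation). Cohorts are the parameter-recovery
harness for the whole statistical layer.

## Reference counts

`impaFociCounts()` ships the per-group cell and foci counts of three
published IMPα modulation experiments (markers PSPC1, SFPQ, DsRed2-PSPC1;
full-length, ΔIBB and ED variants of IMPα2/4/6 against GFP controls). They
are inputs to the contingency layer: the package recomputes all printed
foci-positive percentages, odds ratios and Wald confidence bounds from these
raw counts, which is both a worked example and an acceptance check
(`scripts/acceptance.R`).

## Problem sizes and determinism

The test-suite simulations use one 20-cell tile per acquisition regime for
segmentation scoring, 5-cell tiles for oracle comparisons, cohorts of
2 000–20 000 cells for distributional calibration, 200 replicates for CI
coverage and 1 000 for type-I error — sizes at which the binomial bounds in
the assertions have comfortable margins. All randomness flows through
explicit seeds (`withSeed` restores the caller's RNG state), seeds derived
from a base seed stay below 2³¹, and `runPipeline()` writes fixed-format
CSVs (ratios to 3 decimals, percentages to 1, p-values to 4) so identical
configurations give byte-identical artifacts.

## Known limitations

* Watershed cell partitioning assumes one nucleus per cell; multinucleated
  cells become multiple records.
* The relative focus threshold uses the nucleus median, which is robust to
  foci occupying < 50% of the nucleus but will drift in pathological cases
  where they dominate it.
* GEE sandwich errors are asymptotic in the number of clusters; with very
  few cells per group the variances can be non-estimable and are returned
  as `NA` with the group flagged.
* The Bonferroni divisor is the number of experimental groups, mirroring
  the convention of the tables this package reproduces, which is more
  conservative per comparison than dividing by the number of tests actually
  performed within a family.
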