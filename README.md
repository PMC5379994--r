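# SpeckleQuant

High-throughput 3D quantification of intranuclear foci (paraspeckles) and
nuclear protein accumulation from multi-channel confocal z-series.

## The problem

Paraspeckles are discrete nuclear bodies marked by DBHS proteins (PSPC1,
SFPQ, NONO). Whether a cargo protein reaches the nucleus — and whether it is
recruited into these foci — depends on the importin-α (IMPα) transport
machinery, and the per-cell variability of foci counts (typically 5–20 per
nucleus) is large enough that only thousands of cells give usable contrasts.
Manual cropping and mid-plane ratio measurements do not scale and are biased
by bright substructure.

SpeckleQuant implements the full analysis chain for this kind of experiment:

1. **Segmentation** (`detectNuclei`, `detectCells`, `detectFoci`,
   `linkHierarchy`): intensity thresholds, 26-connected components with
   per-slice hole filling, and a seeded 3D watershed partition the field
   into cells, one nucleus per cell, and intranuclear foci, linked
   hierarchically (focus → nucleus → cell). Volumes are physical (μm³),
   computed on anisotropic voxels.
2. **Gating** (`excludeEdgeNuclei`, `dropCellsWithoutNuclei`,
   `calibrateGfpThreshold`, `applyGfpGate`): nuclei touching the stack
   border are removed, then orphan cells, then a per-cell mean-GFP
   transfection gate whose threshold is the (1 − f) quantile of the control
   cells (default f = 1%) — controls can bypass the gate.
3. **Features** (`computeFnc`, `computeFocusFeatures`,
   `summarizeCellFoci`): for each cell, the nuclear accumulation endpoint

   F_n/c = mean(channel | nucleus voxels) / mean(channel | cytoplasm voxels),

   where the cytoplasm is the 3D cell minus its nucleus, plus per-focus
   volume/intensity features and per-cell foci summaries.
4. **Statistics** (`percentPositive`, `oddsRatio`, `geometricMeanCI`,
   `gmRatioRegression`, `geeRatio`, `bonferroniThreshold`,
   `intensityFncCorrelation`, `pcaGroupSummary`): three outcome types —
   binary foci positivity analysed by Wald odds ratios
   (exp(ln OR ± 1.96·√Σ1/nᵢⱼ)); per-cell counts and continuous outcomes
   analysed as natural-log linear models whose exponentiated coefficients
   are geometric-mean ratios; per-focus outcomes analysed by generalized
   estimating equations (identity link on ln values, exchangeable working
   correlation, cell-clustered sandwich errors). Significance is flagged at
   α divided by the number of experimental groups.
5. **Synthetic data** (`generateStack`, `generateCohort`): a seeded
   generator renders fields of ellipsoidal nuclei with cytoplasmic shells
   and Gaussian-blob foci, with voxel-level ground truth, under a
   high-quality "galvo" or degraded "resonance" acquisition regime; a
   tabular cohort generator draws the per-cell/per-focus tables directly
   with known effect sizes.

`runPipeline()` ties the stages together from a YAML/list configuration and
writes CSV artifacts plus a provenance log; re-running an identical
configuration reproduces byte-identical outputs.
`inst/scripts/focipipe.R` is a thin command-line wrapper
(`simulate`, `segment`, `run`, `stats`).

## Worked example

The package ships the per-group cell counts from three published IMPα
modulation experiments (`impaFociCounts()`). The contingency layer
reproduces the reported effect of the dominant-negative IMPα2ΔIBB construct
on endogenous PSPC1 foci:

```r
library(SpeckleQuant)
counts <- impaFociCounts()
pspc1 <- subset(counts, marker == "PSPC1" & reference_group == "GFP-IMPa2-FL")
tab <- contingencyTable(pspc1$group, pspc1$cells_positive,
                        pspc1$cells_total, "GFP-IMPa2-FL")
percentPositive(tab)
#>            group  percent
#> 1   GFP-IMPa2-FL 54.81928
#> 2 GFP-IMPa2-dIBB 27.74566
#> 3   GFP-IMPa2-ED 45.96950
oddsRatio(tab)
#>            group    reference        or    ci_low   ci_high      p_value
#> 1   GFP-IMPa2-FL GFP-IMPa2-FL 1.0000000        NA        NA           NA
#> 2 GFP-IMPa2-dIBB GFP-IMPa2-FL 0.3164835 0.2205723 0.4540997 4.224709e-10
#> 3   GFP-IMPa2-ED GFP-IMPa2-FL 0.7012141 0.4909104 1.0016108 5.104321e-02
```

Cells expressing the ΔIBB truncation are foci-positive about a third as
often as full-length IMPα2 cells (OR 0.316, 95% CI 0.221–0.454), while the
transport-competent ED control is not significantly different — the
nuclear-import capacity of IMPα2 controls PSPC1 delivery into paraspeckles.

The imaging layer runs the same way on any 3-channel stack; on a synthetic
field with known ground truth:

```r
sim <- generateStack(imageSpec(nCells = 20L, seed = 1L))   # ~30 s total
seg <- segmentStack(sim$stack, segmentationParams())
seg
#> SegmentationResult: 20 cells, 20 nuclei, 119 foci
cells <- buildCellTable(seg, sim$stack)
exp(mean(log(cells$F_n_over_c)))   # generator target was 2.69
#> [1] 2.797725
```

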