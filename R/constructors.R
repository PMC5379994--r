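#' Create a VoxelStack
#'
#' @param intensities 4D numeric array (z, y, x, channel), or a list of 3D
#'   arrays (one per channel) sharing a shape.
#' @param voxelSize numeric(3), voxel size (z, y, x) in micrometres.
#' @param channelRoles character, one role per channel (e.g. \code{"nuclear"},
#'   \code{"cell_marker"}, \code{"foci_marker"}).
#' @return A \linkS4class{VoxelStack}.
#' @examples
#' a <- array(runif(2 * 4 * 4), c(2, 4, 4, 1))
#' voxelStack(a, c(0.5, 0.2, 0.2), "nuclear")
#' @export
voxelStack <- function(intensities, voxelSize, channelRoles) {
  if (is.list(intensities)) {
    d <- dim(intensities[[1]])
    intensities <- array(unlist(intensities, use.names = FALSE),
                         c(d, length(intensities)))
  }
  if (length(dim(intensities)) == 3L)
    dim(intensities) <- c(dim(intensities), 1L)
  new("VoxelStack", intensities = intensities,
      voxelSize = as.numeric(voxelSize),
      channelRoles = as.character(channelRoles))
}

#' Create an ImageSpec
#'
#' Defaults describe one galvo-scanned tile of 20 adherent cells at
#' 0.2 x 0.2 um in-plane sampling with a 0.5 um z-step; see
#' \linkS4class{ImageSpec} for the meaning of every field.
#'
#' @param shape,voxelSize,nCells,nucleusRadiusRange,cytoplasmThicknessRange
#'   Field geometry; see \linkS4class{ImageSpec}.
#' @param fociPi,fociLambda,focusVolumeMeanlog,focusVolumeSdlog Foci laws.
#' @param channelGains,fncTarget,fociContrast,backgroundLevel,gfpSdlog
#'   Intensity model.
#' @param noiseRegime,borderFraction,seed Acquisition noise, border placement
#'   and reproducibility.
#' @return An \linkS4class{ImageSpec}.
#' @examples
#' imageSpec(nCells = 5L, seed = 7L)
#' @export
imageSpec <- function(shape = c(24L, 384L, 384L),
                      voxelSize = c(0.5, 0.2, 0.2),
                      nCells = 20L,
                      nucleusRadiusRange = c(2.0, 3.0),
                      cytoplasmThicknessRange = c(0.8, 1.6),
                      fociPi = 0.7,
                      fociLambda = 8,
                      focusVolumeMeanlog = log(0.22),
                      focusVolumeSdlog = 0.5,
                      channelGains = c(nuclear = 120, cell_marker = 25,
                                       foci_marker = 20),
                      fncTarget = 2.69,
                      fociContrast = 3,
                      noiseRegime = c("galvo", "resonance"),
                      borderFraction = 0,
                      backgroundLevel = 2,
                      gfpSdlog = 0.2,
                      seed = 1L) {
  noiseRegime <- match.arg(noiseRegime)
  new("ImageSpec",
      shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
      nCells = as.integer(nCells),
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      cytoplasmThicknessRange = as.numeric(cytoplasmThicknessRange),
      fociPi = fociPi, fociLambda = fociLambda,
      focusVolumeMeanlog = focusVolumeMeanlog,
      focusVolumeSdlog = focusVolumeSdlog,
      channelGains = as.numeric(channelGains),
      fncTarget = fncTarget, fociContrast = fociContrast,
      noiseRegime = noiseRegime, borderFraction = borderFraction,
      backgroundLevel = backgroundLevel, gfpSdlog = gfpSdlog,
      seed = as.integer(seed))
}

#' Create a CohortSpec
#'
#' @param groups data.frame of per-group generative parameters; see
#'   \linkS4class{CohortSpec}. Convenience: missing law columns are filled
#'   with the defaults \code{pi = 0.7}, \code{lambda = 8},
#'   \code{fnc_gm = 2.69}, \code{fnc_sdlog = 0.45},
#'   \code{volume_meanlog = log(0.22)}, \code{volume_sdlog = 0.5}.
#' @param withinCellSdlog,markerGm,markerSdlog,markerFncSlope,focusIntensityGm,seed
#'   See \linkS4class{CohortSpec}.
#' @return A \linkS4class{CohortSpec}.
#' @examples
#' cohortSpec(data.frame(group = c("FL", "dIBB"), n = 100,
#'                       pi = c(0.55, 0.28)))
#' @export
cohortSpec <- function(groups,
                       withinCellSdlog = 0.3,
                       markerGm = 12,
                       markerSdlog = 0.4,
                       markerFncSlope = 0,
                       focusIntensityGm = 90,
                       seed = 1L) {
  fill <- c(pi = 0.7, lambda = 8, fnc_gm = 2.69, fnc_sdlog = 0.45,
            volume_meanlog = log(0.22), volume_sdlog = 0.5)
  for (nm in names(fill))
    if (is.null(groups[[nm]])) groups[[nm]] <- fill[[nm]]
  groups$group <- as.character(groups$group)
  new("CohortSpec", groups = groups, withinCellSdlog = withinCellSdlog,
      markerGm = markerGm, markerSdlog = markerSdlog,
      markerFncSlope = markerFncSlope, focusIntensityGm = focusIntensityGm,
      seed = as.integer(seed))
}

#' Create SegmentationParams
#'
#' @param nucleusThreshold,cellThreshold,focusThreshold,focusThresholdMode,focusMultiplier,minNucleusVolume,minFocusVolume,splitTouchingNuclei,seedMinDistance
#'   See \linkS4class{SegmentationParams}.
#' @return A \linkS4class{SegmentationParams}.
#' @examples
#' segmentationParams(nucleusThreshold = 60)
#' @export
segmentationParams <- function(nucleusThreshold = 60,
                               cellThreshold = 10,
                               focusThreshold = 120,
                               focusThresholdMode = c("relative", "absolute"),
                               focusMultiplier = 2,
                               minNucleusVolume = 10,
                               minFocusVolume = 0.04,
                               splitTouchingNuclei = FALSE,
                               seedMinDistance = 1) {
  focusThresholdMode <- match.arg(focusThresholdMode)
  new("SegmentationParams",
      nucleusThreshold = nucleusThreshold, cellThreshold = cellThreshold,
      focusThreshold = focusThreshold,
      focusThresholdMode = focusThresholdMode,
      focusMultiplier = focusMultiplier,
      minNucleusVolume = minNucleusVolume, minFocusVolume = minFocusVolume,
      splitTouchingNuclei = splitTouchingNuclei,
      seedMinDistance = seedMinDistance)
}

#' Create a GateConfig
#'
#' @param excludeEdgeAxes,gfpGateMode,gfpThreshold,controlPassFraction,applyGateToControls,controlGroups
#'   See \linkS4class{GateConfig}.
#' @return A \linkS4class{GateConfig}.
#' @examples
#' gateConfig(gfpGateMode = "manual", gfpThreshold = 15)
#' @export
gateConfig <- function(excludeEdgeAxes = c("x", "y", "z"),
                       gfpGateMode = c("control_calibrated", "manual"),
                       gfpThreshold = NA_real_,
                       controlPassFraction = 0.01,
                       applyGateToControls = FALSE,
                       controlGroups = character()) {
  gfpGateMode <- match.arg(gfpGateMode)
  new("GateConfig", excludeEdgeAxes = excludeEdgeAxes,
      gfpGateMode = gfpGateMode, gfpThreshold = gfpThreshold,
      controlPassFraction = controlPassFraction,
      applyGateToControls = applyGateToControls,
      controlGroups = as.character(controlGroups))
}
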