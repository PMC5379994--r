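#' @import methods
#' @importFrom stats lm model.matrix pnorm prcomp qnorm qpois qt rbinom
#'   rlnorm rnorm rpois runif sd cor median quantile relevel
#' @importFrom utils read.csv write.csv head
#' @useDynLib SpeckleQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Multi-channel 3D fluorescence stack
#'
#' Container for a confocal z-series: a 4D intensity array with dimensions
#' (z, y, x, channel), the physical voxel size in micrometres, and the role
#' of each channel. Recognised roles are \code{"nuclear"} (DNA stain such as
#' DAPI/Draq5), \code{"cell_marker"} (cell body / transfection marker such as
#' GFP-IMPa) and \code{"foci_marker"} (the paraspeckle marker, e.g. PSPC1,
#' SFPQ or DsRed2-PSPC1). Additional roles are carried through unchanged.
#'
#' @slot intensities numeric 4D array, dims (z, y, x, channel), non-negative.
#' @slot voxelSize numeric(3), voxel edge lengths (z, y, x) in micrometres.
#' @slot channelRoles character, one role per channel.
#' @export
setClass("VoxelStack",
  representation(
    intensities = "array",
    voxelSize = "numeric",
    channelRoles = "character"
  )
)

setValidity("VoxelStack", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 4L)
    return("'intensities' must be a 4D array (z, y, x, channel)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be three positive values (z, y, x) in um")
  if (length(object@channelRoles) != d[4L])
    return("one channel role required per channel")
  if (anyDuplicated(object@channelRoles))
    return("channel roles must be unique")
  if (any(object@intensities < 0))
    return("intensities must be non-negative")
  TRUE
})

#' Labelled segmentation volumes with object hierarchy
#'
#' Result of cell/nucleus/focus detection: three integer label volumes
#' sharing the stack's (z, y, x) shape (background 0, objects 1..n), the
#' focus -> nucleus -> cell hierarchy table, and per-object statistics
#' (voxel counts, physical volumes, bounding boxes and per-channel intensity
#' sums/means) computed once at link time.
#'
#' @slot cellLabels,nucleusLabels,focusLabels integer 3D label arrays.
#' @slot hierarchy data.frame with columns \code{focus_id}, \code{nucleus_id},
#'   \code{cell_id} (one row per retained focus).
#' @slot nucleusMap data.frame mapping \code{nucleus_id} to \code{cell_id}.
#' @slot cellStats,nucleusStats,focusStats per-object feature tables.
#' @slot voxelSize numeric(3) voxel size (z, y, x) in micrometres.
#' @slot droppedFoci integer, foci discarded for lack of any nucleus overlap.
#' @export
setClass("SegmentationResult",
  representation(
    cellLabels = "array",
    nucleusLabels = "array",
    focusLabels = "array",
    hierarchy = "data.frame",
    nucleusMap = "data.frame",
    cellStats = "data.frame",
    nucleusStats = "data.frame",
    focusStats = "data.frame",
    voxelSize = "numeric",
    droppedFoci = "integer"
  )
)

setValidity("SegmentationResult", function(object) {
  dc <- dim(object@cellLabels)
  if (!identical(dc, dim(object@nucleusLabels)) ||
      !identical(dc, dim(object@focusLabels)))
    return("label volumes must share one (z, y, x) shape")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be three positive values")
  h <- object@hierarchy
  if (nrow(h) && anyDuplicated(h$focus_id))
    return("each focus must have exactly one nucleus parent")
  nm <- object@nucleusMap
  if (nrow(nm) && anyDuplicated(nm$nucleus_id))
    return("each nucleus may have at most one cell parent")
  TRUE
})

#' Voxel-level ground truth for a synthetic stack
#'
#' @slot cellLabels,nucleusLabels,focusLabels integer 3D label arrays; focus
#'   voxels lie inside their parent nucleus, nucleus voxels inside their cell.
#' @slot cells data.frame, one row per cell: \code{cell_id}, \code{group},
#'   \code{foci_count}, \code{fnc_true} (noise-free foci-marker F_n/c),
#'   \code{border} (nucleus touches a stack face), \code{gfp_mean_true}.
#' @slot foci data.frame, one row per focus: \code{focus_id}, \code{cell_id},
#'   \code{volume_um3} (rendered voxel volume).
#' @slot voxelSize numeric(3) in micrometres.
#' @export
setClass("GroundTruth",
  representation(
    cellLabels = "array",
    nucleusLabels = "array",
    focusLabels = "array",
    cells = "data.frame",
    foci = "data.frame",
    voxelSize = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  f <- object@focusLabels
  nl <- object@nucleusLabels
  cl <- object@cellLabels
  if (any(f > 0 & nl == 0))
    return("every focus voxel must lie inside a nucleus")
  if (any(nl > 0 & cl == 0))
    return("every nucleus voxel must lie inside a cell")
  TRUE
})

#' Synthetic stack specification
#'
#' Parameters of the synthetic-field generator. Defaults emulate a single
#' galvo-scanned confocal tile of adherent HeLa-like cells: flattened
#' ellipsoidal nuclei, a cytoplasmic shell, and bright intranuclear foci
#' whose per-cell frequency follows a zero-inflated law (probability
#' \code{fociPi} of being foci-positive, zero-truncated Poisson mean
#' \code{fociLambda} among positive cells, consistent with the 5-20 foci
#' typically seen per nucleus) and whose volumes are log-normal with a
#' geometric mean around 0.22 um^3.
#'
#' @slot shape integer(3) stack shape (z, y, x) in voxels.
#' @slot voxelSize numeric(3) voxel size (z, y, x) in micrometres.
#' @slot nCells integer, number of cells to place.
#' @slot nucleusRadiusRange numeric(2), in-plane nucleus semi-axis range (um).
#' @slot cytoplasmThicknessRange numeric(2), cytoplasm shell thickness (um).
#' @slot fociPi numeric, probability a cell is foci-positive.
#' @slot fociLambda numeric, Poisson mean of the zero-truncated count law.
#' @slot focusVolumeMeanlog,focusVolumeSdlog log-normal focus volume law (um^3).
#' @slot channelGains numeric(3): nuclear-stain, cell-marker and foci-marker
#'   (cytoplasmic baseline) signal levels in detector units.
#' @slot fncTarget numeric, nucleoplasm/cytoplasm intensity ratio rendered in
#'   the foci-marker channel.
#' @slot fociContrast numeric, mean focus intensity as a multiple of the
#'   nucleoplasm level.
#' @slot noiseRegime \code{"galvo"} (slow, high-quality scan) or
#'   \code{"resonance"} (fast scan: 4x read noise, 2x Poisson scaling).
#' @slot borderFraction fraction of nuclei intentionally crossing a stack face.
#' @slot backgroundLevel numeric, auto-fluorescence floor (detector units).
#' @slot gfpSdlog numeric, log-scale spread of per-cell cell-marker brightness.
#' @slot seed integer random seed.
#' @export
setClass("ImageSpec",
  representation(
    shape = "integer",
    voxelSize = "numeric",
    nCells = "integer",
    nucleusRadiusRange = "numeric",
    cytoplasmThicknessRange = "numeric",
    fociPi = "numeric",
    fociLambda = "numeric",
    focusVolumeMeanlog = "numeric",
    focusVolumeSdlog = "numeric",
    channelGains = "numeric",
    fncTarget = "numeric",
    fociContrast = "numeric",
    noiseRegime = "character",
    borderFraction = "numeric",
    backgroundLevel = "numeric",
    gfpSdlog = "numeric",
    seed = "integer"
  )
)

setValidity("ImageSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape <= 0L))
    return("'shape' must be three positive voxel counts (z, y, x)")
  if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  if (object@nCells < 0L) return("'nCells' must be >= 0")
  if (object@fociPi < 0 || object@fociPi > 1)
    return("'fociPi' must lie in [0, 1]")
  if (object@fociLambda <= 0) return("'fociLambda' must be positive")
  if (object@focusVolumeSdlog < 0) return("'focusVolumeSdlog' must be >= 0")
  if (object@borderFraction < 0 || object@borderFraction > 1)
    return("'borderFraction' must lie in [0, 1]")
  if (!object@noiseRegime %in% c("galvo", "resonance"))
    return("'noiseRegime' must be 'galvo' or 'resonance'")
  if (diff(object@nucleusRadiusRange) < 0 ||
      any(object@nucleusRadiusRange <= 0))
    return("'nucleusRadiusRange' must be positive and non-decreasing")
  TRUE
})

#' Tabular cohort specification
#'
#' Per-group generative parameters for simulating the per-cell / per-focus
#' tables directly, without rendering any image. Used to validate the
#' statistical layer against known effect sizes.
#'
#' @slot groups data.frame with one row per group and columns \code{group},
#'   \code{n} (cells), \code{pi} (foci-positive probability), \code{lambda}
#'   (truncated-Poisson mean), \code{fnc_gm} (geometric-mean F_n/c),
#'   \code{fnc_sdlog} (log-scale SD), \code{volume_meanlog},
#'   \code{volume_sdlog} (per-focus volume law, um^3).
#' @slot withinCellSdlog numeric, SD of the per-cell random effect added to
#'   log focus volumes/intensities (induces within-cell correlation).
#' @slot markerGm,markerSdlog log-normal law of the per-cell importin-marker
#'   mean intensity.
#' @slot markerFncSlope numeric, slope linking centred log marker intensity
#'   to log F_n/c (sets the sign of the marker-to-F_n/c correlation).
#' @slot focusIntensityGm geometric mean of per-focus mean voxel intensity.
#' @slot seed integer random seed.
#' @export
setClass("CohortSpec",
  representation(
    groups = "data.frame",
    withinCellSdlog = "numeric",
    markerGm = "numeric",
    markerSdlog = "numeric",
    markerFncSlope = "numeric",
    focusIntensityGm = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  g <- object@groups
  need <- c("group", "n", "pi", "lambda", "fnc_gm", "fnc_sdlog",
            "volume_meanlog", "volume_sdlog")
  if (!all(need %in% names(g)))
    return(paste("'groups' must have columns:", paste(need, collapse = ", ")))
  if (any(g$n <= 0)) return("cells per group must be positive")
  if (any(g$pi < 0 | g$pi > 1)) return("'pi' must lie in [0, 1]")
  if (any(g$lambda <= 0)) return("'lambda' must be positive")
  if (any(g$fnc_gm <= 0)) return("'fnc_gm' must be positive")
  if (any(g$fnc_sdlog < 0) || any(g$volume_sdlog < 0))
    return("log-scale SDs must be >= 0")
  if (anyDuplicated(g$group)) return("group names must be unique")
  TRUE
})

#' Segmentation parameters
#'
#' Intensity thresholds and size filters for cell/nucleus/focus detection.
#' Thresholds are configuration values (they are tuned per experiment, never
#' auto-estimated); \code{\link{otsuThreshold}} is available as an explicit
#' initialiser. \code{focusThreshold} is used when
#' \code{focusThresholdMode = "absolute"}; in \code{"relative"} mode a voxel
#' is a focus candidate when its foci-marker intensity is at least
#' \code{focusMultiplier} times the median foci-marker intensity of its
#' nucleus (falling back to the absolute threshold if that median is zero).
#'
#' @slot nucleusThreshold,cellThreshold,focusThreshold absolute intensity
#'   thresholds (detector units); \code{cellThreshold} is the low
#'   auto-fluorescence gate that captures every cell body.
#' @slot focusThresholdMode \code{"absolute"} or \code{"relative"}.
#' @slot focusMultiplier numeric, relative-mode multiplier.
#' @slot minNucleusVolume,minFocusVolume minimum object volumes (um^3).
#' @slot splitTouchingNuclei logical; separate touching nuclei by watershed
#'   on the Euclidean distance transform.
#' @slot seedMinDistance numeric (um), minimum distance-transform height for
#'   a watershed seed when splitting.
#' @export
setClass("SegmentationParams",
  representation(
    nucleusThreshold = "numeric",
    cellThreshold = "numeric",
    focusThreshold = "numeric",
    focusThresholdMode = "character",
    focusMultiplier = "numeric",
    minNucleusVolume = "numeric",
    minFocusVolume = "numeric",
    splitTouchingNuclei = "logical",
    seedMinDistance = "numeric"
  )
)

setValidity("SegmentationParams", function(object) {
  if (object@nucleusThreshold < 0 || object@cellThreshold < 0 ||
      object@focusThreshold < 0)
    return("thresholds must be >= 0")
  if (object@minNucleusVolume < 0 || object@minFocusVolume < 0)
    return("minimum volumes must be >= 0")
  if (!object@focusThresholdMode %in% c("absolute", "relative"))
    return("'focusThresholdMode' must be 'absolute' or 'relative'")
  if (object@focusMultiplier <= 0) return("'focusMultiplier' must be > 0")
  TRUE
})

#' Gating configuration
#'
#' Post-segmentation filters: edge-nucleus exclusion, orphan-cell removal and
#' the transfection (mean cell-marker intensity) gate. In
#' \code{"control_calibrated"} mode the gate threshold is the empirical
#' (1 - \code{controlPassFraction}) quantile of control-cell mean marker
#' intensity, operationalising "detected cell number approaches zero in the
#' controls" as a deterministic quantile rule.
#'
#' @slot excludeEdgeAxes character subset of \code{c("x", "y", "z")}.
#' @slot gfpGateMode \code{"manual"} or \code{"control_calibrated"}.
#' @slot gfpThreshold manual-mode threshold (mean intensity per cell).
#' @slot controlPassFraction target fraction of control cells allowed above a
#'   calibrated threshold.
#' @slot applyGateToControls logical; when \code{FALSE} the gate is withheld
#'   from control-labelled records.
#' @slot controlGroups character, group labels treated as controls.
#' @export
setClass("GateConfig",
  representation(
    excludeEdgeAxes = "character",
    gfpGateMode = "character",
    gfpThreshold = "numeric",
    controlPassFraction = "numeric",
    applyGateToControls = "logical",
    controlGroups = "character"
  )
)

setValidity("GateConfig", function(object) {
  if (!all(object@excludeEdgeAxes %in% c("x", "y", "z")))
    return("'excludeEdgeAxes' must be a subset of c('x','y','z')")
  if (!object@gfpGateMode %in% c("manual", "control_calibrated"))
    return("'gfpGateMode' must be 'manual' or 'control_calibrated'")
  if (object@controlPassFraction < 0 || object@controlPassFraction > 1)
    return("'controlPassFraction' must lie in [0, 1]")
  TRUE
})
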