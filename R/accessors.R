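#' @name accessors
#' @title Accessors for SpeckleQuant objects
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param x a \linkS4class{VoxelStack}, \linkS4class{SegmentationResult} or
#'   \linkS4class{GroundTruth}.
#' @param role character, a channel role present in \code{channelRoles(x)}.
#' @param which for \code{labelVolume}, one of \code{"cell"},
#'   \code{"nucleus"}, \code{"focus"}.
#' @return \code{voxelSize}: numeric(3) in micrometres. \code{channelRoles}:
#'   character. \code{channelData}: a 3D intensity array. \code{stackShape}:
#'   integer(3). \code{labelVolume}: an integer 3D label array.
#'   \code{hierarchy}: the focus/nucleus/cell linkage data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("channelData", function(x, role) standardGeneric("channelData"))

#' @rdname accessors
#' @export
setGeneric("stackShape", function(x) standardGeneric("stackShape"))

#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x, which) standardGeneric("labelVolume"))

#' @rdname accessors
#' @export
setGeneric("hierarchy", function(x) standardGeneric("hierarchy"))

#' @rdname accessors
#' @export
setGeneric("objectStats", function(x, which) standardGeneric("objectStats"))

#' @rdname accessors
setMethod("voxelSize", "VoxelStack", function(x) x@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "SegmentationResult", function(x) x@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "GroundTruth", function(x) x@voxelSize)

#' @rdname accessors
setMethod("channelRoles", "VoxelStack", function(x) x@channelRoles)

#' @rdname accessors
setMethod("channelData", "VoxelStack", function(x, role) {
  i <- match(role, x@channelRoles)
  if (is.na(i))
    stop("channel role '", role, "' not present (have: ",
         paste(x@channelRoles, collapse = ", "), ")")
  d <- dim(x@intensities)
  array(x@intensities[, , , i], d[1:3])
})

#' @rdname accessors
setMethod("stackShape", "VoxelStack",
          function(x) dim(x@intensities)[1:3])

#' @rdname accessors
setMethod("stackShape", "SegmentationResult", function(x) dim(x@cellLabels))

#' @rdname accessors
setMethod("stackShape", "GroundTruth", function(x) dim(x@cellLabels))

.pickLabels <- function(x, which) {
  switch(match.arg(which, c("cell", "nucleus", "focus")),
         cell = x@cellLabels, nucleus = x@nucleusLabels,
         focus = x@focusLabels)
}

#' @rdname accessors
setMethod("labelVolume", "SegmentationResult", .pickLabels)

#' @rdname accessors
setMethod("labelVolume", "GroundTruth", .pickLabels)

#' @rdname accessors
setMethod("hierarchy", "SegmentationResult", function(x) x@hierarchy)

#' @rdname accessors
setMethod("objectStats", "SegmentationResult", function(x, which) {
  switch(match.arg(which, c("cell", "nucleus", "focus")),
         cell = x@cellStats, nucleus = x@nucleusStats,
         focus = x@focusStats)
})

#' @rdname accessors
#' @export
setGeneric("groundTruthCells", function(x) standardGeneric("groundTruthCells"))

#' @rdname accessors
setMethod("groundTruthCells", "GroundTruth", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("groundTruthFoci", function(x) standardGeneric("groundTruthFoci"))

#' @rdname accessors
setMethod("groundTruthFoci", "GroundTruth", function(x) x@foci)

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@intensities)
  cat("VoxelStack:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "channel(s)\n")
  cat("  voxel size (z, y, x):",
      paste(format(object@voxelSize), collapse = " x "), "um\n")
  cat("  channels:", paste(object@channelRoles, collapse = ", "), "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:",
      nrow(object@cellStats), "cells,",
      nrow(object@nucleusStats), "nuclei,",
      nrow(object@focusStats), "foci\n")
  if (object@droppedFoci > 0L)
    cat("  (", object@droppedFoci, "foci dropped: no nucleus overlap )\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cells), "cells,",
      nrow(object@foci), "foci\n")
})
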