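#' Exclude cells whose nucleus touches the stack border
#'
#' A nucleus whose bounding box touches the first or last voxel plane along
#' any configured axis is likely truncated, so its cell is removed. The test
#' uses the nucleus (not the cell) bounding box. Record order is preserved
#' and per-axis exclusion counts are attached as an attribute and reported.
#'
#' @param cells per-cell data.frame carrying nucleus bounding-box columns
#'   \code{nuc_z0}, \code{nuc_z1}, \code{nuc_y0}, \code{nuc_y1},
#'   \code{nuc_x0}, \code{nuc_x1} (1-based voxel indices).
#' @param shape integer(3), the stack shape (z, y, x) in voxels.
#' @param config a \linkS4class{GateConfig}; only \code{excludeEdgeAxes} is
#'   used.
#' @return The filtered data.frame, with attribute \code{"exclusion_log"}
#'   (data.frame of per-axis counts).
#' @examples
#' df <- data.frame(cell_id = 1:2, nuc_z0 = c(1L, 3L), nuc_z1 = c(4L, 6L),
#'                  nuc_y0 = 5L, nuc_y1 = 9L, nuc_x0 = 5L, nuc_x1 = 9L)
#' excludeEdgeNuclei(df, c(10L, 20L, 20L), gateConfig())
#' @export
excludeEdgeNuclei <- function(cells, shape, config = gateConfig()) {
  need <- c("nuc_z0", "nuc_z1", "nuc_y0", "nuc_y1", "nuc_x0", "nuc_x1")
  stopifnot(all(need %in% names(cells)))
  axes <- config@excludeEdgeAxes
  touch <- list(
    z = cells$nuc_z0 <= 1L | cells$nuc_z1 >= shape[1],
    y = cells$nuc_y0 <= 1L | cells$nuc_y1 >= shape[2],
    x = cells$nuc_x0 <= 1L | cells$nuc_x1 >= shape[3])
  drop <- rep(FALSE, nrow(cells))
  log <- data.frame(axis = character(), excluded = integer())
  for (ax in axes) {
    hit <- touch[[ax]] & !is.na(touch[[ax]])
    log <- rbind(log, data.frame(axis = ax, excluded = sum(hit & !drop)))
    drop <- drop | hit
  }
  out <- cells[!drop, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Remove cells without a linked nucleus
#'
#' Idempotent; records whose \code{nucleus_id} is missing (or, if that column
#' is absent, whose nucleus bounding box is missing) are dropped.
#'
#' @param cells per-cell data.frame with a \code{nucleus_id} column.
#' @return The filtered data.frame.
#' @examples
#' dropCellsWithoutNuclei(data.frame(cell_id = 1:3,
#'                                   nucleus_id = c(1L, NA, 2L)))
#' @export
dropCellsWithoutNuclei <- function(cells) {
  if ("nucleus_id" %in% names(cells))
    return(cells[!is.na(cells$nucleus_id), , drop = FALSE])
  if ("nuc_z0" %in% names(cells))
    return(cells[!is.na(cells$nuc_z0), , drop = FALSE])
  cells
}

#' Calibrate the transfection gate on control cells
#'
#' Returns the empirical (1 - \code{controlPassFraction}) quantile (type 1,
#' an order statistic) of control per-cell mean marker intensity. Applying
#' the (strict) gate back to the controls then leaves at most
#' \code{ceiling(controlPassFraction * n)} control cells, which is the
#' deterministic counterpart of tuning the threshold until the detected cell
#' number "approaches zero" in the controls.
#'
#' @param controlCells data.frame of control cells with a \code{gfp_mean}
#'   column (per-cell mean cell-marker intensity).
#' @param config a \linkS4class{GateConfig}.
#' @return The threshold (numeric scalar).
#' @examples
#' calibrateGfpThreshold(data.frame(gfp_mean = 1:5),
#'                       gateConfig(controlPassFraction = 0))
#' @export
calibrateGfpThreshold <- function(controlCells, config = gateConfig()) {
  if (!nrow(controlCells))
    stop("no control cells available to calibrate the gate; ",
         "use gfpGateMode = 'manual' with an explicit 'gfpThreshold'")
  stopifnot("gfp_mean" %in% names(controlCells))
  as.numeric(quantile(controlCells$gfp_mean,
                      probs = 1 - config@controlPassFraction, type = 1,
                      names = FALSE))
}

#' Apply the transfection (mean marker intensity) gate
#'
#' Retains cells whose per-cell mean marker intensity is strictly greater
#' than \code{threshold}. When \code{applyGateToControls} is \code{FALSE},
#' records whose \code{group} is in \code{controlGroups} bypass the gate, so
#' non-/mock-transfected controls stay analysable with the same base
#' detection parameters.
#'
#' @param cells per-cell data.frame with \code{gfp_mean} (and \code{group} if
#'   controls bypass the gate).
#' @param threshold numeric gate threshold (finite).
#' @param config a \linkS4class{GateConfig}.
#' @return The gated data.frame.
#' @examples
#' applyGfpGate(data.frame(gfp_mean = c(1, 10), group = "t"), 5,
#'              gateConfig())
#' @export
applyGfpGate <- function(cells, threshold, config = gateConfig()) {
  stopifnot(is.finite(threshold), "gfp_mean" %in% names(cells))
  pass <- cells$gfp_mean > threshold
  if (!config@applyGateToControls && length(config@controlGroups) &&
      "group" %in% names(cells))
    pass <- pass | cells$group %in% config@controlGroups
  cells[pass, , drop = FALSE]
}

#' Run the full gating chain
#'
#' Fixed composition: edge-nucleus exclusion, then orphan-cell removal, then
#' the transfection gate (calibrated on controls unless manual). Counts in
#' and out of every stage are recorded so they reconcile exactly.
#'
#' @param cells per-cell data.frame (see \code{\link{buildCellTable}}).
#' @param shape integer(3) stack shape in voxels.
#' @param config a \linkS4class{GateConfig}.
#' @return A list: \code{cells} (the gated table), \code{threshold} (the gate
#'   used, or \code{NA} when no gate could be applied), and \code{log}
#'   (data.frame of stage, cells_in, cells_out).
#' @examples
#' # see vignette("specklequant-methods")
#' @export
applyGates <- function(cells, shape, config = gateConfig()) {
  log <- data.frame(stage = character(), cells_in = integer(),
                    cells_out = integer())
  note <- function(stage, nin, nout)
    rbind(log, data.frame(stage = stage, cells_in = nin, cells_out = nout))

  n0 <- nrow(cells)
  cells <- excludeEdgeNuclei(cells, shape, config)
  log <- note("edge_exclusion", n0, nrow(cells))

  n1 <- nrow(cells)
  cells <- dropCellsWithoutNuclei(cells)
  log <- note("orphan_removal", n1, nrow(cells))

  n2 <- nrow(cells)
  threshold <- NA_real_
  if (config@gfpGateMode == "manual") {
    threshold <- config@gfpThreshold
  } else {
    ctrl <- cells[cells$group %in% config@controlGroups, , drop = FALSE]
    if (nrow(ctrl)) threshold <- calibrateGfpThreshold(ctrl, config)
  }
  if (is.finite(threshold))
    cells <- applyGfpGate(cells, threshold, config)
  log <- note("gfp_gate", n2, nrow(cells))

  list(cells = cells, threshold = threshold, log = log)
}
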