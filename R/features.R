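#' Per-cell nuclear and cytoplasmic mean intensities and their ratio
#'
#' For each segmented cell, the cytoplasm is the cell minus its nucleus.
#' F_n is the mean intensity of \code{channel} over nucleus voxels, F_c over
#' cytoplasm voxels, and F_n/c their ratio — the per-cell nuclear-
#' accumulation endpoint. Because both compartments are segmented in full 3D,
#' bright substructures (such as foci) in either compartment enter the means.
#' Cells with an empty cytoplasmic shell get an undefined ratio and are
#' flagged rather than erroring; they are excluded from F_n/c summaries.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param stack the matching \linkS4class{VoxelStack}.
#' @param channel channel role to quantify (default the foci marker).
#' @return data.frame: \code{cell_id}, \code{nucleus_id}, \code{F_n},
#'   \code{F_c}, \code{F_n_over_c}, \code{zero_cytoplasm}.
#' @examples
#' # see vignette("specklequant-methods")
#' @export
computeFnc <- function(seg, stack, channel = "foci_marker") {
  if (!channel %in% channelRoles(stack))
    stop("channel role '", channel, "' not present in the stack")
  ch <- channelData(stack, channel)
  nucSums <- labelSums(labelVolume(seg, "nucleus"), ch)
  cellSums <- labelSums(labelVolume(seg, "cell"), ch)
  nm <- seg@nucleusMap
  out <- data.frame(cell_id = cellSums$id)
  out$nucleus_id <- nm$nucleus_id[match(out$cell_id, nm$cell_id)]
  ni <- match(out$nucleus_id, nucSums$id)
  nVox <- nucSums$voxel_count[ni]
  nSum <- nucSums$intensity_sum[ni]
  cVox <- cellSums$voxel_count - ifelse(is.na(nVox), 0L, nVox)
  cSum <- cellSums$intensity_sum - ifelse(is.na(nSum), 0, nSum)
  out$F_n <- nSum / nVox
  out$F_c <- ifelse(cVox > 0, cSum / cVox, NA_real_)
  out$F_n_over_c <- ifelse(!is.na(out$F_c) & out$F_c > 0,
                           out$F_n / out$F_c, NA_real_)
  out$zero_cytoplasm <- !is.na(out$nucleus_id) & cVox == 0L
  out
}

#' Per-focus volume and intensity features
#'
#' Volume is the voxel count scaled by the physical voxel volume;
#' \code{mean_intensity} and \code{sum_intensity} are taken over the focus
#' voxels in the foci-marker channel.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param stack the matching \linkS4class{VoxelStack}.
#' @param channel channel role to quantify (default the foci marker).
#' @return data.frame: \code{focus_id}, \code{cell_id}, \code{nucleus_id},
#'   \code{volume_um3}, \code{mean_intensity}, \code{sum_intensity}.
#' @examples
#' # see vignette("specklequant-methods")
#' @export
computeFocusFeatures <- function(seg, stack, channel = "foci_marker") {
  ch <- channelData(stack, channel)
  s <- labelSums(labelVolume(seg, "focus"), ch)
  h <- hierarchy(seg)
  data.frame(
    focus_id = s$id,
    cell_id = h$cell_id[match(s$id, h$focus_id)],
    nucleus_id = h$nucleus_id[match(s$id, h$focus_id)],
    volume_um3 = s$voxel_count * prod(voxelSize(seg)),
    mean_intensity = s$intensity_sum / s$voxel_count,
    sum_intensity = s$intensity_sum)
}

#' Summarise foci per cell
#'
#' Sums focus volumes and intensities within each cell; cells with no foci
#' get zeros and \code{foci_positive = FALSE}. Per-cell foci summaries are
#' reported over foci-positive cells only in the group tables (zero sums
#' carry no information on the log scale).
#'
#' @param focusTable per-focus data.frame with \code{cell_id},
#'   \code{volume_um3} and \code{sum_intensity} columns (see
#'   \code{\link{computeFocusFeatures}}).
#' @param cellIds integer vector of all cell ids to summarise (cells absent
#'   from \code{focusTable} get zero rows).
#' @return data.frame: \code{cell_id}, \code{foci_count},
#'   \code{sum_foci_volume}, \code{sum_foci_intensity}, \code{foci_positive}.
#' @examples
#' foc <- data.frame(cell_id = c(1, 1, 2), volume_um3 = c(.1, .2, .3),
#'                   sum_intensity = c(90, 80, 70))
#' summarizeCellFoci(foc, 1:3)
#' @export
summarizeCellFoci <- function(focusTable, cellIds) {
  out <- data.frame(cell_id = cellIds, foci_count = 0L,
                    sum_foci_volume = 0, sum_foci_intensity = 0)
  ft <- focusTable[!is.na(focusTable$cell_id), , drop = FALSE]
  if (nrow(ft)) {
    cnt <- table(ft$cell_id)
    sv <- rowsum(ft$volume_um3, ft$cell_id)
    si <- rowsum(ft$sum_intensity, ft$cell_id)
    i <- match(out$cell_id, as.integer(names(cnt)))
    out$foci_count <- ifelse(is.na(i), 0L, as.integer(cnt)[i])
    j <- match(out$cell_id, as.integer(rownames(sv)))
    out$sum_foci_volume <- ifelse(is.na(j), 0, sv[j, 1])
    out$sum_foci_intensity <- ifelse(is.na(j), 0, si[j, 1])
  }
  out$foci_positive <- out$foci_count > 0L
  out
}

#' Assemble the per-cell record table
#'
#' Joins F_n/c, whole-cell channel means, nucleus bounding boxes (for edge
#' exclusion) and per-cell foci summaries into the flat table consumed by the
#' gating and statistics layers.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param stack the matching \linkS4class{VoxelStack}.
#' @param fncChannel channel role for the F_n/c endpoint.
#' @param group group label attached to every record.
#' @return data.frame with one row per segmented cell: identifiers, group,
#'   \code{F_n}, \code{F_c}, \code{F_n_over_c}, \code{zero_cytoplasm},
#'   per-channel whole-cell means (\code{mean_<role>}), \code{gfp_mean},
#'   foci summaries and nucleus bounding-box columns \code{nuc_*}.
#' @examples
#' # see vignette("specklequant-methods")
#' @export
buildCellTable <- function(seg, stack, fncChannel = "foci_marker",
                           group = "sample") {
  cs <- objectStats(seg, "cell")
  fnc <- computeFnc(seg, stack, fncChannel)
  foc <- computeFocusFeatures(seg, stack, fncChannel)
  fs <- summarizeCellFoci(foc, cs$id)
  out <- data.frame(cell_id = cs$id, group = group)
  out$nucleus_id <- fnc$nucleus_id[match(out$cell_id, fnc$cell_id)]
  for (col in c("F_n", "F_c", "F_n_over_c", "zero_cytoplasm"))
    out[[col]] <- fnc[[col]][match(out$cell_id, fnc$cell_id)]
  for (rl in channelRoles(stack))
    out[[paste0("mean_", rl)]] <- cs[[paste0("mean_", rl)]]
  out$gfp_mean <- if ("cell_marker" %in% channelRoles(stack))
    out$mean_cell_marker else NA_real_
  for (col in c("foci_count", "sum_foci_volume", "sum_foci_intensity",
                "foci_positive"))
    out[[col]] <- fs[[col]][match(out$cell_id, fs$cell_id)]
  ns <- objectStats(seg, "nucleus")
  ni <- match(out$nucleus_id, ns$id)
  out$nuc_z0 <- ns$z0[ni]; out$nuc_z1 <- ns$z1[ni]
  out$nuc_y0 <- ns$y0[ni]; out$nuc_y1 <- ns$y1[ni]
  out$nuc_x0 <- ns$x0[ni]; out$nuc_x1 <- ns$x1[ni]
  out
}
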