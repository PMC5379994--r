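#' Detect nuclei in the nuclear-stain channel
#'
#' Voxels at or above \code{nucleusThreshold} are grouped into 26-connected
#' components; holes are filled slice-by-slice in z (so nucleolar voids do
#' not fragment a nucleus while adjacent cells cannot be bridged in 3D);
#' components smaller than \code{minNucleusVolume} (um^3) are discarded.
#' With \code{splitTouchingNuclei = TRUE}, touching components are separated
#' by a watershed on the anisotropic Euclidean distance transform, seeded at
#' distance maxima at least \code{seedMinDistance} um from the component
#' boundary.
#'
#' The threshold is deliberately generous in practice (set low enough to
#' capture dim nuclei); a threshold below the global background produces one
#' component spanning most of the volume, which is reported as a warning.
#'
#' @param stack a \linkS4class{VoxelStack} with a \code{"nuclear"} channel.
#' @param params a \linkS4class{SegmentationParams}.
#' @return Integer 3D label array (0 = background), labels compacted to 1..n.
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' nuc <- detectNuclei(sim$stack, segmentationParams())
#' max(nuc)
#' @export
detectNuclei <- function(stack, params) {
  ch <- channelData(stack, "nuclear")
  vs <- voxelSize(stack)
  mask <- ch >= params@nucleusThreshold
  if (!any(mask)) return(array(0L, dim(ch)))
  mask <- fillHolesBySlice(mask)
  lab <- labelComponents(mask)
  lab <- .dropSmall(lab, params@minNucleusVolume, prod(vs))
  if (any(lab > 0L)) {
    counts <- labelSums(lab)
    if (max(counts$voxel_count) > 0.5 * length(lab))
      warning("one nucleus component spans >50% of the volume; ",
              "'nucleusThreshold' is likely below the background level")
  }
  if (params@splitTouchingNuclei && any(lab > 0L))
    lab <- .splitByDistance(lab, vs, params@seedMinDistance)
  compactLabels(lab)
}

.dropSmall <- function(lab, minVolume, voxvol) {
  if (minVolume <= 0 || !any(lab > 0L)) return(lab)
  counts <- labelSums(lab)
  bad <- counts$id[counts$voxel_count * voxvol < minVolume]
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab
}

# Watershed split of touching objects on the (negated) distance transform.
# Seeds are the connected high-distance cores of each component: voxels
# whose distance to the boundary reaches at least 60% of the component
# maximum (and seedMinDistance), a plateau-robust alternative to literal
# local maxima on a discretised anisotropic transform.
.splitByDistance <- function(lab, vs, seedMinDistance) {
  mask <- lab > 0L
  edt <- distanceTransform(mask, vs)
  comp <- labelComponents(mask)
  ids <- comp[mask]
  compMax <- tapply(edt[mask], ids, max)
  height <- pmax(0.6 * compMax[as.character(ids)], seedMinDistance)
  core <- array(FALSE, dim(mask))
  core[mask] <- edt[mask] >= height
  if (!any(core)) return(lab)
  seeds <- labelComponents(core)
  seededWatershed(-edt, seeds, mask)
}

#' Detect cell bodies around detected nuclei
#'
#' The cell foreground is the union of voxels at or above the (low,
#' auto-fluorescence level) \code{cellThreshold} in the cell-marker channel
#' and all nucleus voxels, so that every cell is captured whether or not it
#' is transfected. The foreground is then partitioned among the nuclei by a
#' seeded watershed on the inverted cell-marker intensity, giving exactly one
#' connected cell region per nucleus; foreground not reachable from any
#' nucleus is discarded. When no \code{"cell_marker"} channel is present the
#' nuclear channel is used as the growth cost instead.
#'
#' Cells whose region equals their nucleus (empty cytoplasmic shell) are
#' permitted; they are flagged downstream when F_n/c is computed.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param nuclei integer label array from \code{\link{detectNuclei}}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return Integer 3D label array; cell labels match their seed nucleus
#'   labels.
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' nuc <- detectNuclei(sim$stack, segmentationParams())
#' cells <- detectCells(sim$stack, nuc, segmentationParams())
#' @export
detectCells <- function(stack, nuclei, params) {
  roles <- channelRoles(stack)
  ch <- if ("cell_marker" %in% roles) channelData(stack, "cell_marker")
        else channelData(stack, "nuclear")
  mask <- (ch >= params@cellThreshold) | (nuclei > 0L)
  seededWatershed(-ch, nuclei, mask)
}

#' Detect intranuclear foci
#'
#' Detection is restricted to voxels inside detected nuclei. In
#' \code{"absolute"} mode a voxel is a candidate when its foci-marker
#' intensity is at least \code{focusThreshold}; in \code{"relative"} mode,
#' when it is at least \code{focusMultiplier} times the median foci-marker
#' intensity of its own nucleus (a nucleus with zero median falls back to
#' the absolute threshold). Candidates are grouped by 26-connectivity and
#' components smaller than \code{minFocusVolume} (um^3) are discarded.
#'
#' Raising the threshold can only shrink the candidate set, so the number of
#' detected foci never increases with the threshold.
#'
#' @param stack a \linkS4class{VoxelStack} with a \code{"foci_marker"}
#'   channel.
#' @param nuclei integer label array from \code{\link{detectNuclei}}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return Integer 3D label array of foci, labels 1..n.
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' nuc <- detectNuclei(sim$stack, segmentationParams())
#' foci <- detectFoci(sim$stack, nuc, segmentationParams())
#' @export
detectFoci <- function(stack, nuclei, params) {
  ch <- channelData(stack, "foci_marker")
  vs <- voxelSize(stack)
  inNuc <- nuclei > 0L
  if (!any(inNuc)) return(array(0L, dim(ch)))
  if (params@focusThresholdMode == "absolute") {
    cand <- inNuc & (ch >= params@focusThreshold)
  } else {
    ids <- nuclei[inNuc]
    med <- tapply(ch[inNuc], ids, median)
    thr <- params@focusMultiplier * med
    thr[med == 0] <- params@focusThreshold
    thrVox <- thr[as.character(ids)]
    cand <- array(FALSE, dim(ch))
    cand[inNuc] <- ch[inNuc] >= thrVox
  }
  lab <- labelComponents(cand)
  compactLabels(.dropSmall(lab, params@minFocusVolume, prod(vs)))
}

#' Link cells, nuclei and foci into one hierarchy
#'
#' Assigns each nucleus to the cell with maximal voxel overlap and each focus
#' to the nucleus found at its intensity-weighted centroid (ties broken by
#' larger overlap, then lower nucleus label). A focus whose centroid falls
#' outside every nucleus is assigned by maximal overlap; with no overlap at
#' all it is dropped and counted in \code{droppedFoci}. Per-object voxel
#' counts, physical volumes, bounding boxes and per-channel intensity
#' sums/means are computed once and stored.
#'
#' @param cells,nuclei,foci integer label arrays sharing one shape.
#' @param stack the \linkS4class{VoxelStack} the labels were derived from.
#' @return A \linkS4class{SegmentationResult}.
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' p <- segmentationParams()
#' nuc <- detectNuclei(sim$stack, p)
#' seg <- linkHierarchy(detectCells(sim$stack, nuc, p), nuc,
#'                      detectFoci(sim$stack, nuc, p), sim$stack)
#' hierarchy(seg)
#' @export
linkHierarchy <- function(cells, nuclei, foci, stack) {
  stopifnot(identical(dim(cells), dim(nuclei)),
            identical(dim(cells), dim(foci)))
  vs <- voxelSize(stack)
  roles <- channelRoles(stack)

  # nucleus -> cell by maximal overlap
  ovNC <- labelOverlap(nuclei, cells)
  nucleusMap <- data.frame(nucleus_id = integer(), cell_id = integer())
  if (nrow(ovNC)) {
    ovNC <- ovNC[order(ovNC$a, -ovNC$n, ovNC$b), ]
    best <- ovNC[!duplicated(ovNC$a), ]
    nucleusMap <- data.frame(nucleus_id = best$a, cell_id = best$b)
  }

  # focus -> nucleus at the intensity-weighted centroid
  fch <- if ("foci_marker" %in% roles) channelData(stack, "foci_marker")
         else channelData(stack, roles[1])
  fids <- sort(unique(foci[foci > 0L]))
  dropped <- 0L
  hier <- data.frame(focus_id = integer(), nucleus_id = integer(),
                     cell_id = integer())
  if (length(fids)) {
    d <- dim(foci)
    w <- which(foci > 0L)
    idv <- foci[w]
    wt <- fch[w]
    z <- ((w - 1L) %% d[1]) + 1L
    r <- (w - 1L) %/% d[1]
    y <- (r %% d[2]) + 1L
    x <- (r %/% d[2]) + 1L
    sw <- rowsum(wt, idv)
    # fall back to unweighted centroid for an all-zero-intensity focus
    zero <- sw[, 1] <= 0
    if (any(zero)) {
      w1 <- rep(1, length(wt))
      sw1 <- rowsum(w1, idv)
      sw[zero, 1] <- sw1[zero, 1]
      wt[idv %in% as.integer(rownames(sw))[zero]] <- 1
    }
    cz <- rowsum(wt * z, idv)[, 1] / sw[, 1]
    cy <- rowsum(wt * y, idv)[, 1] / sw[, 1]
    cx <- rowsum(wt * x, idv)[, 1] / sw[, 1]
    ovFN <- labelOverlap(foci, nuclei)
    rows <- vector("list", length(fids))
    for (k in seq_along(fids)) {
      fid <- fids[k]
      key <- as.character(fid)
      iz <- pmin(pmax(as.integer(round(cz[key])), 1L), d[1])
      iy <- pmin(pmax(as.integer(round(cy[key])), 1L), d[2])
      ix <- pmin(pmax(as.integer(round(cx[key])), 1L), d[3])
      nid <- nuclei[iz, iy, ix]
      if (nid == 0L) {
        cand <- ovFN[ovFN$a == fid, , drop = FALSE]
        if (!nrow(cand)) { dropped <- dropped + 1L; next }
        cand <- cand[order(-cand$n, cand$b), , drop = FALSE]
        nid <- cand$b[1]
      }
      cid <- nucleusMap$cell_id[match(nid, nucleusMap$nucleus_id)]
      rows[[k]] <- data.frame(focus_id = fid, nucleus_id = nid,
                              cell_id = if (is.na(cid)) NA_integer_ else cid)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) hier <- do.call(rbind, rows)
  }
  if (dropped > 0L)
    message(dropped, " foci dropped (no nucleus overlap)")

  # clear labels of dropped foci so the label volume matches the hierarchy
  if (dropped > 0L) {
    keepIds <- hier$focus_id
    foci[!(foci %in% c(0L, keepIds))] <- 0L
  }

  perObject <- function(lab) {
    st <- labelSums(lab)
    if (!nrow(st)) {
      st <- data.frame(id = integer(), voxel_count = integer(),
                       volume_um3 = numeric())
    } else {
      st$volume_um3 <- st$voxel_count * prod(vs)
    }
    for (rl in roles) {
      chv <- channelData(stack, rl)
      s <- labelSums(lab, chv)
      st[[paste0("sum_", rl)]] <- s$intensity_sum[match(st$id, s$id)]
      st[[paste0("mean_", rl)]] <- st[[paste0("sum_", rl)]] / st$voxel_count
    }
    bb <- labelBoundingBoxes(lab)
    merge(st, bb, by = "id", all.x = TRUE, sort = TRUE)
  }

  new("SegmentationResult",
      cellLabels = cells, nucleusLabels = nuclei, focusLabels = foci,
      hierarchy = hier, nucleusMap = nucleusMap,
      cellStats = perObject(cells), nucleusStats = perObject(nuclei),
      focusStats = perObject(foci), voxelSize = vs,
      droppedFoci = dropped)
}

#' Object-level precision and recall against ground truth
#'
#' Greedy one-to-one matching between detected and ground-truth objects in
#' decreasing order of voxel overlap; a pair is accepted when its
#' intersection-over-union is at least \code{minIoU} (the standard
#' instance-matching criterion). A detection inflated by attached noise, or
#' one component merging several true objects, therefore fails to match.
#'
#' @param detected,truth integer label arrays of the same shape.
#' @param minIoU minimum intersection-over-union for a match.
#' @return A list: \code{n_detected}, \code{n_truth}, \code{n_matched},
#'   \code{precision}, \code{recall}, and \code{jaccard} (per matched pair).
#' @examples
#' a <- array(0L, c(2, 8, 8)); a[, 2:4, 2:4] <- 1L
#' matchObjects(a, a)$recall
#' @export
matchObjects <- function(detected, truth, minIoU = 0.5) {
  nd <- length(unique(detected[detected > 0L]))
  nt <- length(unique(truth[truth > 0L]))
  ov <- labelOverlap(detected, truth)
  if (!nrow(ov))
    return(list(n_detected = nd, n_truth = nt, n_matched = 0L,
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_, jaccard = numeric()))
  sd_ <- labelSums(detected)
  st_ <- labelSums(truth)
  ov$sizeD <- sd_$voxel_count[match(ov$a, sd_$id)]
  ov$sizeT <- st_$voxel_count[match(ov$b, st_$id)]
  ov <- ov[order(-ov$n, ov$a, ov$b), ]
  usedD <- integer(0)
  usedT <- integer(0)
  jac <- numeric(0)
  matched <- 0L
  for (k in seq_len(nrow(ov))) {
    if (ov$a[k] %in% usedD || ov$b[k] %in% usedT) next
    iou <- ov$n[k] / (ov$sizeD[k] + ov$sizeT[k] - ov$n[k])
    if (iou < minIoU) next
    usedD <- c(usedD, ov$a[k])
    usedT <- c(usedT, ov$b[k])
    jac <- c(jac, iou)
    matched <- matched + 1L
  }
  list(n_detected = nd, n_truth = nt, n_matched = matched,
       precision = if (nd) matched / nd else NA_real_,
       recall = if (nt) matched / nt else NA_real_,
       jaccard = jac)
}
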