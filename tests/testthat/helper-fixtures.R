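# Fixtures built in code; all randomness goes through fixed seeds.

# Tiny one-cell stack with hand-placed intensities: the cell is a 1 x 5 x 1
# voxel column, the first two voxels are the nucleus. Foci-marker values are
# chosen so F_n = mean(4, 6) = 5 and F_c = mean(2, 2, 4) = 8/3.
handStack <- function(nucleusVals = c(4, 6), cytoVals = c(2, 2, 4)) {
  shp <- c(1L, length(nucleusVals) + length(cytoVals), 1L)
  foci <- array(0, shp)
  foci[1, , 1] <- c(nucleusVals, cytoVals)
  nuclear <- array(0, shp)
  nuclear[1, seq_along(nucleusVals), 1] <- 100
  cellLab <- array(1L, shp)
  nucLab <- array(0L, shp)
  nucLab[1, seq_along(nucleusVals), 1] <- 1L
  stack <- voxelStack(list(nuclear, foci), c(0.5, 0.2, 0.2),
                      c("nuclear", "foci_marker"))
  list(stack = stack, cells = cellLab, nuclei = nucLab,
       foci = array(0L, shp))
}

# Two ellipsoids (radius r um) fused by a one-voxel-wide bridge along x,
# rendered into the nuclear channel.
fusedSpheresStack <- function(r = 1.5, sep = 4, shape = c(16L, 40L, 64L),
                              voxelSize = c(0.5, 0.2, 0.2)) {
  ctrY <- shape[2] * voxelSize[2] / 2
  ctrZ <- shape[1] * voxelSize[1] / 2
  cx <- shape[3] * voxelSize[3] / 2 + c(-sep / 2, sep / 2)
  zc <- (seq_len(shape[1]) - 0.5) * voxelSize[1]
  yc <- (seq_len(shape[2]) - 0.5) * voxelSize[2]
  xc <- (seq_len(shape[3]) - 0.5) * voxelSize[3]
  mask <- array(FALSE, shape)
  for (cc in cx) {
    q <- outer(outer((zc - ctrZ)^2, (yc - ctrY)^2, `+`), (xc - cc)^2, `+`)
    mask <- mask | (q <= r^2)
  }
  # bridge: single line of voxels between the sphere surfaces
  iz <- round(ctrZ / voxelSize[1])
  iy <- round(ctrY / voxelSize[2])
  ix1 <- round((cx[1] + r) / voxelSize[3])
  ix2 <- round((cx[2] - r) / voxelSize[3])
  mask[iz, iy, (ix1 - 2):(ix2 + 2)] <- TRUE  # overlap both sphere surfaces
  ch <- array(0, shape)
  ch[mask] <- 120
  voxelStack(list(ch), voxelSize, "nuclear")
}

# Map detected labels to ground-truth labels by maximal overlap and return
# the voxel-count ratio detected / truth per matched object.
matchedVolumeRatios <- function(detected, truth) {
  ov <- SpeckleQuant:::labelOverlap(detected, truth)
  ov <- ov[order(ov$a, -ov$n), ]
  best <- ov[!duplicated(ov$a), ]
  ds <- SpeckleQuant:::labelSums(detected)
  ts <- SpeckleQuant:::labelSums(truth)
  ds$voxel_count[match(best$a, ds$id)] /
    ts$voxel_count[match(best$b, ts$id)]
}

# Clustered log-normal per-focus data with a known group ratio and
# within-cell intraclass correlation.
clusteredFociSim <- function(nCellsPerGroup = 120, fociPerCell = 5,
                             ratio = 0.7, icc = 0.4, totalSd = 0.6,
                             seed = 1) {
  set.seed(seed)
  sdB <- sqrt(icc) * totalSd
  sdW <- sqrt(1 - icc) * totalSd
  mk <- function(group, mu, idOffset) {
    cellId <- rep(seq_len(nCellsPerGroup) + idOffset, each = fociPerCell)
    b <- rep(rnorm(nCellsPerGroup, 0, sdB), each = fociPerCell)
    data.frame(group = group, cell_id = cellId,
               value = exp(mu + b + rnorm(length(cellId), 0, sdW)))
  }
  rbind(mk("ref", 0, 0L), mk("test", log(ratio), nCellsPerGroup))
}
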