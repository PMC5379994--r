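#' Generate a synthetic multi-channel stack with voxel-level ground truth
#'
#' Renders a field of adherent cells: axis-aligned ellipsoidal nuclei
#' (flattened in z), a cytoplasmic shell around each nucleus, and bright
#' intranuclear foci drawn as Gaussian blobs truncated at two standard
#' deviations, with the blob amplitude set so that the mean blob intensity
#' exceeds the surrounding nucleoplasm by \code{fociContrast}. The
#' foci-marker channel realises the requested nuclear/cytoplasmic intensity
#' ratio; the cell-marker channel sits at a per-cell transfection level
#' inside cells and at the auto-fluorescence floor elsewhere. Photon (Poisson)
#' and read (Gaussian) noise are applied according to the acquisition regime:
#' \code{"resonance"} uses four times the read noise and twice the Poisson
#' scaling of \code{"galvo"}, reproducing the fast-scanning regime in which
#' reliable foci detection breaks down.
#'
#' Identical \code{spec} (including seed) gives bit-identical output. Nuclei
#' are placed by rejection sampling without overlap; a field too dense to
#' place raises an error.
#'
#' @param spec an \linkS4class{ImageSpec}.
#' @return A list with elements \code{stack} (a \linkS4class{VoxelStack} with
#'   channels \code{nuclear}, \code{cell_marker}, \code{foci_marker}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' sim$stack
#' @export
generateStack <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .renderField(spec))
}

.renderField <- function(spec) {
  shp <- spec@shape
  vs <- spec@voxelSize
  L <- shp * vs                     # physical extent (z, y, x) in um
  voxvol <- prod(vs)
  nc <- spec@nCells

  cellLab <- array(0L, shp)
  nucLab <- array(0L, shp)
  focLab <- array(0L, shp)

  placed <- .placeCells(spec, L)

  # voxel-centre coordinates (um)
  zc <- (seq_len(shp[1]) - 0.5) * vs[1]
  yc <- (seq_len(shp[2]) - 0.5) * vs[2]
  xc <- (seq_len(shp[3]) - 0.5) * vs[3]

  for (i in seq_len(nc)) {
    p <- placed[i, ]
    cs <- c(p$crz, p$cry, p$crx)    # cell semi-axes
    ns <- c(p$nrz, p$nry, p$nrx)    # nucleus semi-axes
    ctr <- c(p$cz, p$cy, p$cx)
    rng <- .bboxRange(ctr, cs, shp, vs)
    if (is.null(rng)) next
    dz <- (zc[rng$z] - ctr[1])
    dy <- (yc[rng$y] - ctr[2])
    dx <- (xc[rng$x] - ctr[3])
    q <- function(semi) {
      outer(outer((dz / semi[1])^2, (dy / semi[2])^2, `+`),
            (dx / semi[3])^2, `+`)
    }
    inCell <- q(cs) <= 1
    inNuc <- q(ns) <= 1
    sub <- cellLab[rng$z, rng$y, rng$x, drop = FALSE]
    sub[inCell] <- i
    cellLab[rng$z, rng$y, rng$x] <- sub
    sub <- nucLab[rng$z, rng$y, rng$x, drop = FALSE]
    sub[inNuc] <- i
    nucLab[rng$z, rng$y, rng$x] <- sub
  }

  # noiseless channels
  bg <- spec@backgroundLevel
  chNuc <- array(bg, shp)
  chNuc[nucLab > 0L] <- spec@channelGains[1]
  gfpLevel <- spec@channelGains[2] * rlnorm(max(nc, 1L), 0, spec@gfpSdlog)
  chCell <- array(bg, shp)
  if (nc > 0L) chCell[cellLab > 0L] <- bg + gfpLevel[cellLab[cellLab > 0L]]
  baseCyto <- spec@channelGains[3]
  baseNucleo <- spec@fncTarget * baseCyto
  chFoci <- array(bg, shp)
  chFoci[cellLab > 0L] <- baseCyto
  chFoci[nucLab > 0L] <- baseNucleo

  # foci
  fociRows <- list()
  fociCount <- integer(nc)
  nextFocus <- 0L
  for (i in seq_len(nc)) {
    p <- placed[i, ]
    blobExcess <- 0
    if (rbinom(1L, 1L, spec@fociPi) == 0L) next
    k <- rtruncpois(1L, spec@fociLambda)
    centres <- matrix(numeric(0), 0L, 3L)
    sigmas <- numeric(0)
    for (f in seq_len(k)) {
      v <- rlnorm(1L, spec@focusVolumeMeanlog, spec@focusVolumeSdlog)
      sigma <- (3 * v / (4 * pi))^(1 / 3) / 2
      ns <- c(p$nrz, p$nry, p$nrx)
      shrink <- pmax(0, 1 - (2 * sigma + 0.1) / ns)
      ctr <- NULL
      for (try in 1:50) {
        u <- rnorm(3L)
        u <- u / sqrt(sum(u^2)) * runif(1L)^(1 / 3)
        cand <- c(p$cz, p$cy, p$cx) + ns * shrink * u
        if (nrow(centres) == 0L ||
            all(sqrt(rowSums(sweep(centres, 2L, cand)^2)) >
                2 * sigma + 2 * sigmas + 0.5)) {
          ctr <- cand
          break
        }
      }
      if (is.null(ctr)) next
      rng <- .bboxRange(ctr, rep(2 * sigma, 3L), shp, vs)
      if (is.null(rng)) next
      dz <- zc[rng$z] - ctr[1]
      dy <- yc[rng$y] - ctr[2]
      dx <- xc[rng$x] - ctr[3]
      r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
      nucSub <- nucLab[rng$z, rng$y, rng$x, drop = FALSE]
      inBlob <- r2 <= (2 * sigma)^2 & nucSub == i
      if (!any(inBlob)) next
      kern <- exp(-r2 / (2 * sigma^2))
      amp <- (spec@fociContrast - 1) * baseNucleo /
        mean(kern[inBlob])
      sub <- chFoci[rng$z, rng$y, rng$x, drop = FALSE]
      sub[inBlob] <- sub[inBlob] + amp * kern[inBlob]
      chFoci[rng$z, rng$y, rng$x] <- sub
      blobExcess <- blobExcess + amp * sum(kern[inBlob])
      nextFocus <- nextFocus + 1L
      sub <- focLab[rng$z, rng$y, rng$x, drop = FALSE]
      sub[inBlob] <- nextFocus
      focLab[rng$z, rng$y, rng$x] <- sub
      centres <- rbind(centres, ctr)
      sigmas <- c(sigmas, sigma)
      fociCount[i] <- fociCount[i] + 1L
      fociRows[[nextFocus]] <- data.frame(
        focus_id = nextFocus, cell_id = i,
        volume_um3 = sum(inBlob) * voxvol)
    }
    # lower the nucleoplasm uniformly so the nucleus mean still realises
    # fncTarget after the bright blobs are added
    if (blobExcess > 0) {
      nucVox <- nucLab == i
      chFoci[nucVox] <- chFoci[nucVox] - blobExcess / sum(nucVox)
    }
  }

  # overlapping blobs may overwrite earlier labels entirely; keep the table
  # consistent with the rendered volume
  fociTab <- if (length(fociRows)) do.call(rbind, fociRows) else
    data.frame(focus_id = integer(), cell_id = integer(),
               volume_um3 = numeric())
  if (nrow(fociTab)) {
    vc <- labelSums(focLab)
    keep <- fociTab$focus_id %in% vc$id
    fociTab <- fociTab[keep, , drop = FALSE]
    fociTab$volume_um3 <-
      vc$voxel_count[match(fociTab$focus_id, vc$id)] * voxvol
    fociCount <- tabulate(fociTab$cell_id, nbins = max(nc, 1L))[seq_len(nc)]
    remap <- compactLabels(focLab)
    fociTab$focus_id <- remap[match(fociTab$focus_id, focLab)]
    o <- order(fociTab$focus_id)
    fociTab <- fociTab[o, , drop = FALSE]
    rownames(fociTab) <- NULL
    focLab <- remap
  }

  # noise-free per-cell F_n/c of the foci-marker channel
  fncTrue <- rep(NA_real_, nc)
  gfpTrue <- rep(NA_real_, nc)
  if (nc > 0L) {
    nucSums <- labelSums(nucLab, chFoci)
    cellSums <- labelSums(cellLab, chFoci)
    gfpSums <- labelSums(cellLab, chCell)
    for (i in seq_len(nc)) {
      nrow_i <- match(i, nucSums$id)
      crow_i <- match(i, cellSums$id)
      if (is.na(nrow_i) || is.na(crow_i)) next
      nv <- nucSums$voxel_count[nrow_i]
      ns <- nucSums$intensity_sum[nrow_i]
      cv <- cellSums$voxel_count[crow_i] - nv
      cssum <- cellSums$intensity_sum[crow_i] - ns
      fncTrue[i] <- if (cv > 0) (ns / nv) / (cssum / cv) else NA_real_
      gfpTrue[i] <- gfpSums$intensity_sum[match(i, gfpSums$id)] /
        gfpSums$voxel_count[match(i, gfpSums$id)]
    }
  }

  border <- rep(FALSE, nc)
  if (nc > 0L) {
    bb <- labelBoundingBoxes(nucLab)
    hit <- bb$z0 == 1L | bb$z1 == shp[1] | bb$y0 == 1L | bb$y1 == shp[2] |
      bb$x0 == 1L | bb$x1 == shp[3]
    border[bb$id] <- hit
  }

  noisy <- function(ch) .applyNoise(ch, spec@noiseRegime)
  stack <- voxelStack(list(noisy(chNuc), noisy(chCell), noisy(chFoci)),
                      vs, c("nuclear", "cell_marker", "foci_marker"))

  cells <- data.frame(
    cell_id = seq_len(nc),
    group = rep("sample", nc),
    foci_count = fociCount,
    fnc_true = fncTrue,
    border = border,
    gfp_mean_true = gfpTrue)

  truth <- new("GroundTruth", cellLabels = cellLab, nucleusLabels = nucLab,
               focusLabels = focLab, cells = cells, foci = fociTab,
               voxelSize = vs)
  list(stack = stack, truth = truth)
}

# Acquisition noise: scaled Poisson photon noise plus Gaussian read noise.
.noiseParams <- list(galvo = c(read_sigma = 6, poisson_gain = 1),
                     resonance = c(read_sigma = 24, poisson_gain = 2))

.applyNoise <- function(ch, regime) {
  pr <- .noiseParams[[regime]]
  g <- pr[["poisson_gain"]]
  n <- length(ch)
  out <- g * rpois(n, as.numeric(ch) / g) +
    rnorm(n, 0, pr[["read_sigma"]])
  out[out < 0] <- 0
  array(out, dim(ch))
}

# Rejection-sampled non-overlapping cell placement. Returns a data.frame of
# centres and semi-axes (um).
.placeCells <- function(spec, L) {
  nc <- spec@nCells
  out <- data.frame(cz = numeric(nc), cy = numeric(nc), cx = numeric(nc),
                    nrz = numeric(nc), nry = numeric(nc), nrx = numeric(nc),
                    crz = numeric(nc), cry = numeric(nc), crx = numeric(nc))
  if (nc == 0L) return(out)
  nBorder <- round(spec@borderFraction * nc)
  margin <- 0.3
  centres <- matrix(numeric(0), 0L, 3L)
  radii <- numeric(0)
  for (i in seq_len(nc)) {
    ok <- FALSE
    for (try in 1:500) {
      nrx <- runif(1L, spec@nucleusRadiusRange[1], spec@nucleusRadiusRange[2])
      nry <- runif(1L, spec@nucleusRadiusRange[1], spec@nucleusRadiusRange[2])
      nrz <- 0.7 * min(nrx, nry)
      th <- runif(1L, spec@cytoplasmThicknessRange[1],
                  spec@cytoplasmThicknessRange[2])
      cs <- c(nrz, nry, nrx) + th
      nr <- c(nrz, nry, nrx)
      # centre bounds keep the nucleus interior; the cytoplasm may be
      # truncated in thin stacks (adherent cells can span the full depth)
      lo0 <- cs + margin
      hi0 <- L - cs - margin
      tight <- lo0 > hi0
      lo0[tight] <- nr[tight] + margin
      hi0[tight] <- L[tight] - nr[tight] - margin
      if (any(lo0 > hi0))
        stop("stack too small for the configured nucleus radii")
      ctr <- c(runif(1L, lo0[1], hi0[1]), runif(1L, lo0[2], hi0[2]),
               runif(1L, lo0[3], hi0[3]))
      if (i <= nBorder) {
        # nucleus deliberately crossing an x or y face
        ax <- sample(2:3, 1L)
        ctr[ax] <- if (runif(1L) < 0.5) runif(1L, 0, 0.5 * nr[ax]) else
          runif(1L, L[ax] - 0.5 * nr[ax], L[ax])
      }
      rmax <- max(cs)
      if (nrow(centres) == 0L ||
          all(sqrt(rowSums(sweep(centres, 2L, ctr)^2)) >
              radii + rmax + margin)) {
        centres <- rbind(centres, ctr)
        radii <- c(radii, rmax)
        out[i, ] <- c(ctr, nrz, nry, nrx, cs)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", nc, " non-overlapping cells in a ",
           paste(round(L, 1), collapse = " x "),
           " um field; reduce nCells or enlarge the stack")
  }
  out
}

# Voxel index ranges covering centre +/- semi (um); NULL if fully outside.
.bboxRange <- function(ctr, semi, shp, vs) {
  lo <- pmax(1L, as.integer(floor((ctr - semi) / vs + 0.5)))
  hi <- pmin(shp, as.integer(ceiling((ctr + semi) / vs + 0.5)))
  if (any(lo > hi)) return(NULL)
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

#' Simulate a tabular per-cell / per-focus cohort
#'
#' Draws the hierarchical tables directly from the generative laws, without
#' rendering images: per cell a foci-positivity indicator (probability
#' \code{pi}), a zero-truncated Poisson focus count, a log-normal F_n/c and a
#' log-normal cell-marker mean intensity (optionally coupled to F_n/c via
#' \code{markerFncSlope}); per focus a log-normal volume and intensity with a
#' shared per-cell random effect so that foci from the same cell are
#' correlated. Used to validate the statistical layer against known effect
#' sizes.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return A list of two data.frames: \code{cells} (columns \code{cell_id},
#'   \code{group}, \code{foci_count}, \code{foci_positive}, \code{fnc},
#'   \code{marker_mean}, \code{sum_foci_volume}, \code{sum_foci_intensity})
#'   and \code{foci} (columns \code{focus_id}, \code{cell_id}, \code{group},
#'   \code{volume_um3}, \code{mean_intensity}, \code{sum_intensity}).
#' @examples
#' coh <- generateCohort(cohortSpec(data.frame(group = c("FL", "dIBB"),
#'                                             n = 50, pi = c(0.6, 0.3))))
#' head(coh$cells)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    g <- spec@groups
    cellList <- vector("list", nrow(g))
    fociList <- vector("list", nrow(g))
    idBase <- 0L
    for (r in seq_len(nrow(g))) {
      n <- g$n[r]
      ids <- idBase + seq_len(n)
      idBase <- idBase + n
      positive <- rbinom(n, 1L, g$pi[r]) == 1L
      count <- integer(n)
      count[positive] <- rtruncpois(sum(positive), g$lambda[r])
      marker <- rlnorm(n, log(spec@markerGm), spec@markerSdlog)
      fnc <- exp(log(g$fnc_gm[r]) +
                   spec@markerFncSlope * (log(marker) - log(spec@markerGm)) +
                   rnorm(n, 0, g$fnc_sdlog[r]))
      cellEff <- rnorm(n, 0, spec@withinCellSdlog)
      tot <- sum(count)
      if (tot > 0L) {
        parent <- rep(seq_len(n), count)
        vol <- exp(g$volume_meanlog[r] + cellEff[parent] +
                     rnorm(tot, 0, g$volume_sdlog[r]))
        mint <- exp(log(spec@focusIntensityGm) + 0.5 * cellEff[parent] +
                      rnorm(tot, 0, 0.15))
        sint <- mint * vol / 0.02    # intensity integrated over the volume
        fociList[[r]] <- data.frame(
          focus_id = NA_integer_, cell_id = ids[parent],
          group = g$group[r], volume_um3 = vol,
          mean_intensity = mint, sum_intensity = sint)
        sv <- rowsum(vol, parent)
        si <- rowsum(sint, parent)
        sumVol <- numeric(n)
        sumInt <- numeric(n)
        sumVol[as.integer(rownames(sv))] <- sv
        sumInt[as.integer(rownames(si))] <- si
      } else {
        sumVol <- numeric(n)
        sumInt <- numeric(n)
      }
      cellList[[r]] <- data.frame(
        cell_id = ids, group = g$group[r], foci_count = count,
        foci_positive = positive, fnc = fnc, marker_mean = marker,
        sum_foci_volume = sumVol, sum_foci_intensity = sumInt)
    }
    cells <- do.call(rbind, cellList)
    foci <- do.call(rbind, fociList)
    if (is.null(foci))
      foci <- data.frame(focus_id = integer(), cell_id = integer(),
                         group = character(), volume_um3 = numeric(),
                         mean_intensity = numeric(),
                         sum_intensity = numeric())
    if (nrow(foci)) foci$focus_id <- seq_len(nrow(foci))
    rownames(cells) <- NULL
    rownames(foci) <- NULL
    list(cells = cells, foci = foci)
  })
}
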