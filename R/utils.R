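# Internal helpers.

# Run expr with a local RNG state: seeds deterministically, then restores
# whatever state the caller had. Keeps all package randomness explicit.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit seed from a base seed.
deriveSeed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}

# Zero-truncated Poisson via inverse CDF on U(P(X=0), 1).
rtruncpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  qpois(runif(n, p0, 1), lambda)
}

# 26-connectivity connected components of a logical 3D array.
labelComponents <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .label3d_cpp(mask, dim(mask))
}

# Anisotropic Euclidean distance transform (um) of a logical 3D array.
distanceTransform <- function(mask, voxelSize) {
  .edt3d_cpp(mask, dim(mask), as.numeric(voxelSize))
}

# Seeded watershed over mask, flooding in order of increasing cost.
seededWatershed <- function(cost, seeds, mask) {
  .watershed3d_cpp(as.numeric(cost), as.integer(seeds), mask, dim(seeds))
}

# Fill 2D holes slice by slice (z): nucleolar voids must not fragment
# nuclei, while filling in 3D could bridge adjacent structures.
fillHolesBySlice <- function(mask) {
  d <- dim(mask)
  m <- aperm(array(as.numeric(mask), d), c(2L, 3L, 1L)) # (y, x, z) frames
  f <- EBImage::fillHull(m)
  aperm(array(f > 0, dim(m)), c(3L, 1L, 2L))
}

# Relabel a label volume to consecutive 1..n (0 stays background).
compactLabels <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# Per-label voxel counts and intensity sums: returns data.frame keyed by id.
labelSums <- function(lab, values = NULL) {
  ids <- lab[lab > 0L]
  if (!length(ids))
    return(data.frame(id = integer(), voxel_count = integer()))
  mx <- max(ids)
  cnt <- tabulate(ids, nbins = mx)
  keep <- which(cnt > 0L)
  out <- data.frame(id = keep, voxel_count = cnt[keep])
  if (!is.null(values)) {
    s <- rowsum(as.numeric(values[lab > 0L]), ids)
    out$intensity_sum <- as.numeric(s[match(keep, as.integer(rownames(s)))])
  }
  out
}

# Bounding boxes (1-based voxel indices) per label: columns id,
# z0, z1, y0, y1, x0, x1.
labelBoundingBoxes <- function(lab) {
  d <- dim(lab)
  w <- which(lab > 0L)
  if (!length(w))
    return(data.frame(id = integer(), z0 = integer(), z1 = integer(),
                      y0 = integer(), y1 = integer(),
                      x0 = integer(), x1 = integer()))
  ids <- lab[w]
  z <- ((w - 1L) %% d[1L]) + 1L
  r <- (w - 1L) %/% d[1L]
  y <- (r %% d[2L]) + 1L
  x <- (r %/% d[2L]) + 1L
  agg <- function(v, f) as.integer(tapply(v, ids, f))
  u <- sort(unique(ids))
  data.frame(id = u,
             z0 = agg(z, min), z1 = agg(z, max),
             y0 = agg(y, min), y1 = agg(y, max),
             x0 = agg(x, min), x1 = agg(x, max))
}

# Overlap (voxel co-occurrence) table of two label volumes; rows with both
# labels > 0. Columns a, b, n.
labelOverlap <- function(a, b) {
  sel <- a > 0L & b > 0L
  if (!any(sel))
    return(data.frame(a = integer(), b = integer(), n = integer()))
  key <- paste(a[sel], b[sel])
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, "", 1L)),
             b = as.integer(vapply(parts, `[`, "", 2L)),
             n = as.integer(tab))
}

#' Otsu threshold of an intensity volume
#'
#' Standard between-class variance maximiser over a 256-bin histogram.
#' Offered as an explicit initialiser for
#' \code{\link{segmentationParams}} thresholds; it is never applied
#' silently by the detection functions.
#'
#' @param x numeric array or vector of intensities.
#' @param nbins number of histogram bins.
#' @return A single threshold on the intensity scale of \code{x}.
#' @examples
#' otsuThreshold(c(rnorm(500, 10), rnorm(500, 100)))
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(nbins, 1L + as.integer((x - rng[1L]) / diff(rng) *
                                              nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  bcv <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}
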