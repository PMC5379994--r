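#' Write a stack as multi-page TIFF files with a JSON sidecar
#'
#' One multi-page (z) 32-bit float TIFF per channel, intensities scaled into
#' [0, 1] by a per-channel factor recorded in the sidecar
#' (\code{stack.json}), together with the voxel size and channel roles.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param dir output directory (created if needed).
#' @param name base name for the files.
#' @return Invisibly, the sidecar path.
#' @examples
#' d <- tempfile(); sim <- generateStack(imageSpec(shape = c(4L, 16L, 16L),
#'                                                 nCells = 0L))
#' writeStack(sim$stack, d)
#' @export
writeStack <- function(stack, dir, name = "stack") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- channelRoles(stack)
  scales <- numeric(length(roles))
  files <- character(length(roles))
  for (i in seq_along(roles)) {
    ch <- channelData(stack, roles[i])
    scales[i] <- max(ch, 1e-12)
    pages <- lapply(seq_len(dim(ch)[1]),
                    function(z) ch[z, , ] / scales[i])
    files[i] <- file.path(dir, paste0(name, "_", roles[i], ".tif"))
    tiff::writeTIFF(pages, files[i], bits.per.sample = 32L)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(name = name, voxel_size_zyx_um = voxelSize(stack),
         shape_zyx = dim(stack@intensities)[1:3],
         channels = data.frame(role = roles, file = basename(files),
                               scale = scales)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a stack written by \code{\link{writeStack}}
#'
#' @param dir directory containing the sidecar and channel TIFFs.
#' @param name base name used when writing.
#' @return A \linkS4class{VoxelStack}.
#' @examples
#' d <- tempfile(); sim <- generateStack(imageSpec(shape = c(4L, 16L, 16L),
#'                                                 nCells = 0L))
#' writeStack(sim$stack, d)
#' readStack(d)
#' @export
readStack <- function(dir, name = "stack") {
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar))
    stop("no stack sidecar found at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shp <- as.integer(meta$shape_zyx)
  chans <- meta$channels
  arrs <- vector("list", nrow(chans))
  for (i in seq_len(nrow(chans))) {
    pages <- tiff::readTIFF(file.path(dir, chans$file[i]), all = TRUE)
    a <- array(0, shp)
    for (z in seq_len(shp[1])) a[z, , ] <- pages[[z]] * chans$scale[i]
    arrs[[i]] <- a
  }
  voxelStack(arrs, as.numeric(meta$voxel_size_zyx_um), chans$role)
}

#' Write the per-cell and per-focus tables
#'
#' @param cells,foci data.frames (the consolidated table layout).
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @examples
#' d <- tempfile()
#' writeObjectTables(data.frame(cell_id = 1), data.frame(focus_id = 1), d)
#' @export
writeObjectTables <- function(cells, foci, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fc <- file.path(dir, "cells.csv")
  ff <- file.path(dir, "foci.csv")
  write.csv(cells, fc, row.names = FALSE)
  write.csv(foci, ff, row.names = FALSE)
  invisible(c(cells = fc, foci = ff))
}

#' Read per-object tables
#'
#' Two layouts are accepted. The consolidated layout written by
#' \code{\link{writeObjectTables}} (\code{cells.csv} + \code{foci.csv}) is
#' read back directly. Otherwise the directory is treated as a per-category
#' export (one CSV per statistic category, comma-separated with a header and
#' an \code{"ID"} key column, the layout produced by reorganising Imaris
#' exports): files whose name contains \code{focus}/\code{foci}/
#' \code{vesicle} are joined into the per-focus table, all others into the
#' per-cell table. Joins are by ID and loss-reporting: IDs missing from some
#' category are dropped and counted.
#'
#' @param path directory of CSV files.
#' @return A list: \code{cells}, \code{foci} (either may be an empty
#'   data.frame), \code{unmatched} (dropped-ID count per table).
#' @examples
#' d <- tempfile()
#' writeObjectTables(data.frame(cell_id = 1), data.frame(focus_id = 1), d)
#' readObjectTables(d)
#' @export
readObjectTables <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files))
    stop("no tables found in ", path)
  bn <- basename(files)
  if (all(c("cells.csv", "foci.csv") %in% bn)) {
    return(list(
      cells = read.csv(file.path(path, "cells.csv")),
      foci = read.csv(file.path(path, "foci.csv")),
      unmatched = c(cells = 0L, foci = 0L)))
  }
  isFocus <- grepl("foc|vesicle", bn, ignore.case = TRUE)
  joinCat <- function(fs) {
    if (!length(fs)) return(list(tab = data.frame(), unmatched = 0L))
    tabs <- lapply(fs, function(f) {
      t <- read.csv(f, check.names = FALSE)
      if (!"ID" %in% names(t))
        stop("file ", basename(f), " has no 'ID' column")
      if (anyDuplicated(t$ID))
        stop("file ", basename(f), " has duplicate IDs")
      t
    })
    joined <- Reduce(function(a, b) merge(a, b, by = "ID"), tabs)
    total <- length(unique(unlist(lapply(tabs, `[[`, "ID"))))
    list(tab = joined[order(joined$ID), , drop = FALSE],
         unmatched = total - nrow(joined))
  }
  cellsJ <- joinCat(files[!isFocus])
  fociJ <- joinCat(files[isFocus])
  if (cellsJ$unmatched + fociJ$unmatched > 0L)
    message(cellsJ$unmatched + fociJ$unmatched,
            " unmatched IDs dropped during table join")
  list(cells = cellsJ$tab, foci = fociJ$tab,
       unmatched = c(cells = cellsJ$unmatched, foci = fociJ$unmatched))
}

#' Write the ground truth of a synthetic stack
#'
#' Label volumes as 16-bit multi-page TIFFs and the per-cell/per-focus truth
#' tables as CSV.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @examples
#' d <- tempfile(); sim <- generateStack(imageSpec(shape = c(4L, 16L, 16L),
#'                                                 nCells = 0L))
#' writeGroundTruth(sim$truth, d)
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- function(lab, nm) {
    pages <- lapply(seq_len(dim(lab)[1]), function(z) lab[z, , ] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, "_labels.tif")),
                    bits.per.sample = 16L)
  }
  wl(truth@cellLabels, "cell")
  wl(truth@nucleusLabels, "nucleus")
  wl(truth@focusLabels, "focus")
  write.csv(groundTruthCells(truth), file.path(dir, "truth_cells.csv"),
            row.names = FALSE)
  write.csv(groundTruthFoci(truth), file.path(dir, "truth_foci.csv"),
            row.names = FALSE)
  invisible(dir)
}
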