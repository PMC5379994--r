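#' Read a YAML run configuration
#'
#' @param path YAML file; see \code{\link{runPipeline}} for the recognised
#'   fields.
#' @return A named list.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("seed: 3", f)
#' readRunConfig(f)$seed
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# deterministic polynomial hash (mod 2^31 - 1) of the serialised config
.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end pipeline
#'
#' Executes simulate (or ingest) -> segment -> link -> gate -> features ->
#' statistics, writing each stage's artifact plus a machine-readable
#' provenance log. Re-running with an identical configuration reproduces
#' byte-identical result CSVs.
#'
#' The configuration is a named list (or a YAML file read with
#' \code{\link{readRunConfig}}) with fields:
#' \describe{
#'   \item{groups}{named list; each entry may override \code{\link{imageSpec}}
#'     arguments (\code{n_cells}, \code{fnc_target}, \code{foci_pi},
#'     \code{foci_lambda}, \code{noise_regime}, \code{border_fraction},
#'     \code{gfp_gain}).}
#'   \item{input_dir}{alternatively, a directory of per-object CSV tables to
#'     ingest instead of simulating (see \code{\link{readObjectTables}}).}
#'   \item{reference}{reference group for all ratios (required).}
#'   \item{control_groups}{groups treated as controls by the gate.}
#'   \item{image}{shared \code{\link{imageSpec}} overrides (shape,
#'     voxel_size, ...).}
#'   \item{segmentation}{\code{\link{segmentationParams}} overrides.}
#'   \item{gate}{\code{\link{gateConfig}} overrides.}
#'   \item{stats}{\code{alpha}, \code{bonferroni_divisor}, \code{gee_corstr},
#'     \code{pca_scale}, \code{count_mode}.}
#'   \item{output_dir}{where artifacts are written (required).}
#'   \item{seed}{base seed; per-group generator seeds are derived from it.}
#' }
#'
#' @param config a named list or the path to a YAML file.
#' @return Invisibly, a list: \code{cells}, \code{foci} (gated tables),
#'   \code{results} (group summary), \code{pca}, \code{gate_threshold},
#'   \code{provenance}.
#' @examples
#' # see vignette("specklequant-methods")
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$output_dir)) stop("config needs 'output_dir'")
  if (is.null(config$reference)) stop("config needs 'reference'")
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- .configHash(config[setdiff(names(config), "output_dir")])

  prov <- list()
  stage <- function(name, params, nIn, nOut)
    prov[[length(prov) + 1L]] <<- list(stage = name, parameters = params,
                                       rows_in = nIn, rows_out = nOut)

  segArgs <- .mapArgs(config$segmentation, c(
    nucleus_threshold = "nucleusThreshold", cell_threshold = "cellThreshold",
    focus_threshold = "focusThreshold",
    focus_threshold_mode = "focusThresholdMode",
    focus_multiplier = "focusMultiplier",
    min_nucleus_volume = "minNucleusVolume",
    min_focus_volume = "minFocusVolume",
    split_touching_nuclei = "splitTouchingNuclei"))
  params <- do.call(segmentationParams, segArgs)

  if (!is.null(config$input_dir)) {
    tabs <- readObjectTables(config$input_dir)
    cells <- tabs$cells
    foci <- tabs$foci
    shape <- as.integer(config$image$shape %||% c(NA, NA, NA))
    stage("ingest", list(input_dir = config$input_dir),
          nrow(cells), nrow(cells))
  } else {
    if (is.null(config$groups)) stop("config needs 'groups' or 'input_dir'")
    cellsL <- fociL <- list()
    cellOffset <- 0L
    shape <- NULL
    for (gi in seq_along(config$groups)) {
      gname <- names(config$groups)[gi]
      ov <- config$groups[[gi]]
      isArgs <- c(.mapArgs(config$image, c(
        shape = "shape", voxel_size = "voxelSize", n_cells = "nCells",
        nucleus_radius_range = "nucleusRadiusRange",
        cytoplasm_thickness_range = "cytoplasmThicknessRange",
        border_fraction = "borderFraction")),
        .mapArgs(ov, c(
          n_cells = "nCells", fnc_target = "fncTarget",
          foci_pi = "fociPi", foci_lambda = "fociLambda",
          noise_regime = "noiseRegime", border_fraction = "borderFraction")))
      isArgs$seed <- deriveSeed(seed, gi)
      spec <- do.call(imageSpec, isArgs)
      sim <- generateStack(spec)
      shape <- stackShape(sim$stack)
      seg <- segmentStack(sim$stack, params)
      ct <- buildCellTable(seg, sim$stack, group = gname)
      ft <- computeFocusFeatures(seg, sim$stack)
      ft$group <- rep(gname, nrow(ft))
      ct$cell_id <- ct$cell_id + cellOffset
      ft$cell_id <- ft$cell_id + cellOffset
      cellOffset <- cellOffset + max(ct$cell_id - cellOffset, 0L)
      cellsL[[gi]] <- ct
      fociL[[gi]] <- ft
      stage(paste0("segment:", gname),
            list(seed = spec@seed, n_cells = spec@nCells,
                 noise_regime = spec@noiseRegime),
            spec@nCells, nrow(ct))
    }
    cells <- do.call(rbind, cellsL)
    foci <- do.call(rbind, fociL)
  }

  gateArgs <- .mapArgs(config$gate, c(
    exclude_edge_axes = "excludeEdgeAxes", gfp_gate_mode = "gfpGateMode",
    gfp_threshold = "gfpThreshold",
    control_pass_fraction = "controlPassFraction",
    apply_gate_to_controls = "applyGateToControls"))
  gateArgs$controlGroups <- as.character(config$control_groups %||%
                                           character())
  gate <- do.call(gateConfig, gateArgs)

  gated <- if (all(c("nuc_z0", "nuc_z1") %in% names(cells)) &&
               !anyNA(shape)) {
    applyGates(cells, shape, gate)
  } else {
    list(cells = cells, threshold = NA_real_,
         log = data.frame(stage = "gating_skipped",
                          cells_in = nrow(cells), cells_out = nrow(cells)))
  }
  for (k in seq_len(nrow(gated$log)))
    stage(gated$log$stage[k], list(threshold = gated$threshold),
          gated$log$cells_in[k], gated$log$cells_out[k])
  cells <- gated$cells
  foci <- foci[!is.na(foci$cell_id) & foci$cell_id %in% cells$cell_id, ,
               drop = FALSE]

  st <- config$stats %||% list()
  results <- summarizeGroups(
    cells, foci, reference = config$reference,
    alpha = st$alpha %||% 0.05,
    bonferroniDivisor = st$bonferroni_divisor %||% NULL,
    countMode = st$count_mode %||% "positive_only",
    geeCorstr = st$gee_corstr %||% "exchangeable")
  pca <- tryCatch(
    resultsPca(results, scale = isTRUE(st$pca_scale)),
    error = function(e) NULL)
  stage("stats", list(reference = config$reference),
        nrow(cells), nrow(results))

  writeObjectTables(cells, foci, outDir)
  .writeResultsCsv(results, file.path(outDir, "results.csv"), hash, seed)
  jsonlite::write_json(
    list(config_hash = hash, seed = seed, stages = prov),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cells = cells, foci = foci, results = results, pca = pca,
                 gate_threshold = gated$threshold, provenance = prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mapArgs <- function(lst, map) {
  if (is.null(lst)) return(list())
  out <- list()
  for (nm in names(lst))
    if (nm %in% names(map)) out[[map[[nm]]]] <- lst[[nm]]
  out
}

#' Segment a stack end to end
#'
#' Convenience wrapper: nuclei, cells, foci, hierarchy.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return A \linkS4class{SegmentationResult}.
#' @examples
#' sim <- generateStack(imageSpec(shape = c(12L, 96L, 96L), nCells = 2L))
#' segmentStack(sim$stack, segmentationParams())
#' @export
segmentStack <- function(stack, params = segmentationParams()) {
  nuclei <- detectNuclei(stack, params)
  cellsLab <- detectCells(stack, nuclei, params)
  fociLab <- detectFoci(stack, nuclei, params)
  linkHierarchy(cellsLab, nuclei, fociLab, stack)
}

# Fixed-format serialisation: ratios/GMs 3 decimals, percentages 1 decimal,
# p-values 4 decimals; keeps re-runs byte-identical.
.writeResultsCsv <- function(results, path, hash, seed) {
  fmt <- results
  pctRow <- grepl("^pct_", fmt$statistic)
  f3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  f1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  fmt$value <- ifelse(pctRow, f1(results$value),
                      ifelse(grepl("^n_", fmt$statistic),
                             sprintf("%d", as.integer(results$value)),
                             f3(results$value)))
  for (col in c("ci_low", "ci_high", "ratio", "ratio_ci_low",
                "ratio_ci_high"))
    fmt[[col]] <- f3(results[[col]])
  fmt$p_value <- ifelse(is.na(results$p_value), "",
                        sprintf("%.4f", results$p_value))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  write.csv(fmt, con, row.names = FALSE)
  invisible(path)
}
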