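mkCells <- function(n, shape = c(20L, 50L, 50L)) {
  data.frame(cell_id = seq_len(n), group = "test",
             nucleus_id = seq_len(n), gfp_mean = 10,
             nuc_z0 = 5L, nuc_z1 = 10L, nuc_y0 = 5L, nuc_y1 = 10L,
             nuc_x0 = 5L, nuc_x1 = 10L)
}

test_that("nuclei touching configured faces are excluded", {
  shape <- c(20L, 50L, 50L)
  cells <- mkCells(10L)
  cells$nuc_z0[1] <- 1L                       # touches z = 1 face
  cells$nuc_y1[2] <- 50L                      # touches y max face
  cells$nuc_x0[3] <- 1L                       # touches x = 1 face
  out <- excludeEdgeNuclei(cells, shape, gateConfig())
  expect_identical(out$cell_id, 4:10)
  log <- attr(out, "exclusion_log")
  expect_identical(sum(log$excluded), 3L)
  # interior bounding boxes are always retained
  expect_identical(nrow(excludeEdgeNuclei(mkCells(4L), shape, gateConfig())),
                   4L)
  # a nucleus spanning z in [1, 5] of a 20-slice stack is excluded
  one <- mkCells(1L); one$nuc_z0 <- 1L; one$nuc_z1 <- 5L
  expect_identical(nrow(excludeEdgeNuclei(one, shape, gateConfig())), 0L)
  # axis configuration is honoured
  cfg <- gateConfig(excludeEdgeAxes = c("y", "x"))
  expect_identical(excludeEdgeNuclei(cells, shape, cfg)$cell_id,
                   c(1L, 4:10))
})

test_that("orphan-cell removal composes with edge exclusion, idempotently", {
  cells <- mkCells(5L)
  cells$nuc_z0[4:5] <- 1L
  filtered <- excludeEdgeNuclei(cells, c(20L, 50L, 50L), gateConfig())
  # simulate orphaning: two other records lose their nucleus
  filtered$nucleus_id[1:2] <- NA_integer_
  once <- dropCellsWithoutNuclei(filtered)
  expect_identical(once$cell_id, 3L)
  expect_identical(dropCellsWithoutNuclei(once), once)
  # no orphans: identity
  intact <- mkCells(3L)
  expect_identical(dropCellsWithoutNuclei(intact), intact)
})

test_that("gate calibration returns the configured control quantile", {
  # pass fraction 0: threshold is the maximum, nothing strictly above
  ctrl <- data.frame(gfp_mean = c(1, 2, 3, 4, 5))
  thr <- calibrateGfpThreshold(ctrl, gateConfig(controlPassFraction = 0))
  expect_identical(thr, 5)
  expect_identical(nrow(applyGfpGate(ctrl, thr, gateConfig())), 0L)
  # uniform controls: about 1% pass at the default fraction
  set.seed(31)
  big <- data.frame(gfp_mean = runif(1e4))
  thr <- calibrateGfpThreshold(big, gateConfig(controlPassFraction = 0.01))
  expect_identical(sum(big$gfp_mean > thr), 100L)
  # degenerate all-equal controls
  same <- data.frame(gfp_mean = rep(7, 20))
  thr <- calibrateGfpThreshold(same, gateConfig(controlPassFraction = 0.01))
  expect_identical(thr, 7)
  expect_identical(nrow(applyGfpGate(same, thr, gateConfig())), 0L)
  expect_error(calibrateGfpThreshold(data.frame(gfp_mean = numeric())[0, ,
                                                                      drop = FALSE],
                                     gateConfig()),
               "manual")
})

test_that("the gate keeps strictly-above records and can bypass controls", {
  set.seed(17)
  cells <- data.frame(cell_id = 1:50,
                      group = rep(c("ctrl", "test"), 25),
                      gfp_mean = runif(50, 0, 20))
  thr <- 9.5
  cfg <- gateConfig(controlGroups = "ctrl", applyGateToControls = FALSE)
  out <- applyGfpGate(cells, thr, cfg)
  # brute force over all records
  expected <- cells[cells$gfp_mean > thr | cells$group == "ctrl", ]
  expect_identical(out, expected)
  # threshold below every cell: identity
  expect_identical(applyGfpGate(cells, -1, cfg), cells)
  # threshold above every cell with gating applied to all: empty tests,
  # controls intact when bypassed
  out2 <- applyGfpGate(cells, 1e6, cfg)
  expect_identical(unique(out2$group), "ctrl")
  cfgAll <- gateConfig(controlGroups = "ctrl", applyGateToControls = TRUE)
  expect_identical(nrow(applyGfpGate(cells, 1e6, cfgAll)), 0L)
  # gating is idempotent
  expect_identical(applyGfpGate(out, thr, cfg), out)
})

test_that("the gating chain reconciles stage counts exactly", {
  cells <- mkCells(12L)
  cells$group <- rep(c("ctrl", "test"), 6)
  cells$gfp_mean <- seq(1, 23, by = 2)
  cells$nuc_x1[1] <- 50L          # one edge exclusion
  res <- applyGates(cells, c(20L, 50L, 50L),
                    gateConfig(controlGroups = "ctrl",
                               controlPassFraction = 0))
  log <- res$log
  expect_identical(log$cells_in[1], 12L)
  expect_identical(log$cells_out[nrow(log)], nrow(res$cells))
  # chained: each stage starts where the previous ended
  expect_identical(log$cells_in[-1], log$cells_out[-nrow(log)])
})
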