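test_that("F_n/c matches hand arithmetic on a fixed voxel layout", {
  fx <- handStack(nucleusVals = c(4, 6), cytoVals = c(2, 2, 4))
  seg <- linkHierarchy(fx$cells, fx$nuclei, fx$foci, fx$stack)
  fnc <- computeFnc(seg, fx$stack, "foci_marker")
  expect_equal(fnc$F_n, 5)
  expect_equal(fnc$F_c, 8 / 3)
  expect_equal(fnc$F_n_over_c, 1.875)
  expect_false(fnc$zero_cytoplasm)
})

test_that("a uniform field gives F_n/c of exactly one", {
  fx <- handStack(nucleusVals = c(7, 7), cytoVals = c(7, 7, 7))
  seg <- linkHierarchy(fx$cells, fx$nuclei, fx$foci, fx$stack)
  expect_equal(computeFnc(seg, fx$stack, "foci_marker")$F_n_over_c, 1)
})

test_that("a missing channel errors and zero cytoplasm is flagged", {
  fx <- handStack()
  seg <- linkHierarchy(fx$cells, fx$nuclei, fx$foci, fx$stack)
  expect_error(computeFnc(seg, fx$stack, "cell_marker"), "not present")
  # cell == nucleus: undefined ratio, flagged not thrown
  seg2 <- linkHierarchy(fx$nuclei, fx$nuclei, fx$foci, fx$stack)
  fnc <- computeFnc(seg2, fx$stack, "foci_marker")
  expect_true(fnc$zero_cytoplasm)
  expect_true(is.na(fnc$F_n_over_c))
})

test_that("scaling a channel scales means and sums but not F_n/c", {
  sim <- generateStack(imageSpec(shape = c(12L, 128L, 128L), nCells = 2L,
                                 seed = 14L))
  seg <- segmentStack(sim$stack, segmentationParams())
  fnc1 <- computeFnc(seg, sim$stack, "foci_marker")
  foc1 <- computeFocusFeatures(seg, sim$stack)
  k <- 3.7
  scaled <- sim$stack
  i <- match("foci_marker", channelRoles(scaled))
  scaled@intensities[, , , i] <- scaled@intensities[, , , i] * k
  # relink so stored per-object sums refer to the scaled stack
  seg2 <- linkHierarchy(labelVolume(seg, "cell"), labelVolume(seg, "nucleus"),
                        labelVolume(seg, "focus"), scaled)
  fnc2 <- computeFnc(seg2, scaled, "foci_marker")
  foc2 <- computeFocusFeatures(seg2, scaled)
  expect_equal(fnc2$F_n, k * fnc1$F_n, tolerance = 1e-12)
  expect_equal(fnc2$F_c, k * fnc1$F_c, tolerance = 1e-12)
  expect_equal(fnc2$F_n_over_c, fnc1$F_n_over_c, tolerance = 1e-12)
  expect_equal(foc2$mean_intensity, k * foc1$mean_intensity,
               tolerance = 1e-12)
  expect_equal(foc2$sum_intensity, k * foc1$sum_intensity,
               tolerance = 1e-12)
  expect_equal(foc2$volume_um3, foc1$volume_um3)
})

test_that("compartment additivity and mean bounds hold per cell", {
  sim <- generateStack(imageSpec(shape = c(16L, 192L, 192L), nCells = 4L,
                                 seed = 15L))
  seg <- segmentStack(sim$stack, segmentationParams())
  cs <- objectStats(seg, "cell")
  ns <- objectStats(seg, "nucleus")
  fnc <- computeFnc(seg, sim$stack, "foci_marker")
  for (k in seq_len(nrow(fnc))) {
    cid <- fnc$cell_id[k]
    nid <- fnc$nucleus_id[k]
    cvox <- cs$voxel_count[match(cid, cs$id)]
    nvox <- ns$voxel_count[match(nid, ns$id)]
    cytoVox <- cvox - nvox
    expect_identical(cvox, nvox + cytoVox)
    wholeMean <- cs$mean_foci_marker[match(cid, cs$id)]
    expect_gte(wholeMean, min(fnc$F_n[k], fnc$F_c[k]) - 1e-9)
    expect_lte(wholeMean, max(fnc$F_n[k], fnc$F_c[k]) + 1e-9)
  }
})

test_that("focus features follow the voxel arithmetic", {
  shp <- c(2L, 4L, 4L)
  vs <- c(0.5, 0.2, 0.2)                 # voxel volume 0.02 um^3
  foci <- array(0, shp)
  lab <- array(0L, shp)
  foci[1, 1, 1] <- 90; lab[1, 1, 1] <- 1L              # 1-voxel focus
  foci[2, 3, 3] <- 80; foci[2, 4, 3] <- 100
  lab[2, 3, 3] <- 2L; lab[2, 4, 3] <- 2L               # {80, 100}
  nucLab <- array(1L, shp)
  stack <- voxelStack(list(array(100, shp), foci), vs,
                      c("nuclear", "foci_marker"))
  seg <- linkHierarchy(nucLab, nucLab, lab, stack)
  ft <- computeFocusFeatures(seg, stack)
  expect_equal(ft$volume_um3, c(0.02, 0.04))
  expect_equal(ft$mean_intensity, c(90, 90))
  expect_equal(ft$sum_intensity, c(90, 180))
  # sum = mean x voxel count within rounding
  expect_equal(ft$sum_intensity,
               ft$mean_intensity * ft$volume_um3 / prod(vs),
               tolerance = 1e-9)
})

test_that("per-cell foci summaries equal brute-force recomputation", {
  coh <- generateCohort(cohortSpec(
    data.frame(group = "g", n = 20L, pi = 0.8), seed = 6L))
  sums <- summarizeCellFoci(coh$foci, coh$cells$cell_id)
  for (k in seq_len(nrow(sums))) {
    rows <- coh$foci[coh$foci$cell_id == sums$cell_id[k], ]
    expect_identical(sums$foci_count[k], nrow(rows))
    expect_equal(sums$sum_foci_volume[k], sum(rows$volume_um3))
    expect_equal(sums$sum_foci_intensity[k], sum(rows$sum_intensity))
    expect_identical(sums$foci_positive[k], nrow(rows) > 0L)
  }
  # direct arithmetic example and the empty case
  direct <- summarizeCellFoci(
    data.frame(cell_id = 1L, volume_um3 = c(0.1, 0.2, 0.3),
               sum_intensity = c(1, 2, 3)), cellIds = 1:2)
  expect_equal(direct$sum_foci_volume, c(0.6, 0))
  expect_identical(direct$foci_count, c(3L, 0L))
  expect_identical(direct$foci_positive, c(TRUE, FALSE))
})

test_that("rendered F_n/c is recovered from the stack within 5%", {
  sim <- generateStack(imageSpec(shape = c(16L, 224L, 224L), nCells = 4L,
                                 fncTarget = 2.69, seed = 26L))
  seg <- segmentStack(sim$stack, segmentationParams())
  ct <- buildCellTable(seg, sim$stack)
  gm <- exp(mean(log(ct$F_n_over_c[!is.na(ct$F_n_over_c)])))
  expect_lt(abs(gm - 2.69) / 2.69, 0.05)
})
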