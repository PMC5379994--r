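# Shared small simulated field: 5 well-separated cells, high-quality scan.
lowNoiseSim <- generateStack(imageSpec(shape = c(16L, 256L, 256L),
                                       nCells = 5L, seed = 21L))
segParams <- segmentationParams()

test_that("an all-zero nuclear channel yields zero nuclei", {
  shp <- c(4L, 16L, 16L)
  stack <- voxelStack(list(array(0, shp)), c(0.5, 0.2, 0.2), "nuclear")
  expect_identical(max(detectNuclei(stack, segParams)), 0L)
})

test_that("separated nuclei are each recovered with high overlap", {
  nuc <- detectNuclei(lowNoiseSim$stack, segParams)
  m <- matchObjects(nuc, labelVolume(lowNoiseSim$truth, "nucleus"))
  expect_identical(m$n_detected, 5L)
  expect_identical(m$n_matched, 5L)
  expect_true(all(m$jaccard > 0.7))
})

test_that("a sub-background threshold triggers the giant-component warning", {
  expect_warning(
    detectNuclei(lowNoiseSim$stack,
                 segmentationParams(nucleusThreshold = 0,
                                    minNucleusVolume = 0)),
    "50%")
})

test_that("fused nuclei are split by the distance-transform watershed", {
  stack <- fusedSpheresStack()
  whole <- detectNuclei(stack, segmentationParams(
    nucleusThreshold = 60, minNucleusVolume = 1,
    splitTouchingNuclei = FALSE))
  expect_identical(max(whole), 1L)
  split <- detectNuclei(stack, segmentationParams(
    nucleusThreshold = 60, minNucleusVolume = 1,
    splitTouchingNuclei = TRUE))
  expect_identical(max(split), 2L)
})

test_that("marker below the gate everywhere leaves cell == nucleus", {
  shp <- c(4L, 20L, 20L)
  nuclear <- array(0, shp)
  nuclear[2:3, 8:12, 8:12] <- 100
  marker <- array(1, shp)  # uniform, below cellThreshold = 10
  stack <- voxelStack(list(nuclear, marker), c(0.5, 0.2, 0.2),
                      c("nuclear", "cell_marker"))
  nuc <- detectNuclei(stack, segmentationParams(minNucleusVolume = 0))
  cel <- detectCells(stack, nuc, segParams)
  expect_identical(cel, nuc)
  seg <- linkHierarchy(cel, nuc, array(0L, shp), stack)
  fnc <- computeFnc(seg, stack, "cell_marker")
  expect_true(all(fnc$zero_cytoplasm))
})

test_that("cell regions match ground truth on a clean field", {
  nuc <- detectNuclei(lowNoiseSim$stack, segParams)
  cel <- detectCells(lowNoiseSim$stack, nuc, segParams)
  expect_identical(length(unique(cel[cel > 0L])), 5L)
  ratios <- matchedVolumeRatios(cel, labelVolume(lowNoiseSim$truth, "cell"))
  expect_true(all(abs(ratios - 1) < 0.2))
  # every cell contains its seed nucleus (labels are shared by construction)
  expect_true(all(cel[nuc > 0L] == nuc[nuc > 0L]))
})

test_that("one marker blob around two nuclei is split into two cells", {
  shp <- c(6L, 24L, 48L)
  nuclear <- array(0, shp)
  nuclear[3:4, 10:14, 8:14] <- 100    # nucleus 1
  nuclear[3:4, 10:14, 34:40] <- 100   # nucleus 2
  marker <- array(0, shp)
  marker[2:5, 6:18, 4:44] <- 30       # one contiguous blob over both
  stack <- voxelStack(list(nuclear, marker), c(0.5, 0.2, 0.2),
                      c("nuclear", "cell_marker"))
  nuc <- detectNuclei(stack, segmentationParams(minNucleusVolume = 0))
  expect_identical(max(nuc), 2L)
  cel <- detectCells(stack, nuc, segParams)
  expect_identical(sort(unique(cel[cel > 0L])), 1:2)
  for (i in 1:2) expect_true(all(cel[nuc == i] == i))
  # the blob was fully partitioned between the two cells
  expect_true(all(cel[marker >= 10] > 0L))
})

test_that("uniform nucleoplasm without blobs yields zero foci", {
  shp <- c(4L, 20L, 20L)
  nuclear <- array(0, shp); nuclear[2:3, 5:15, 5:15] <- 100
  foci <- array(0, shp); foci[2:3, 5:15, 5:15] <- 50
  stack <- voxelStack(list(nuclear, foci), c(0.5, 0.2, 0.2),
                      c("nuclear", "foci_marker"))
  nuc <- detectNuclei(stack, segmentationParams(minNucleusVolume = 0))
  expect_identical(max(detectFoci(stack, nuc, segParams)), 0L)
})

test_that("foci detection is monotone in the absolute threshold", {
  nuc <- detectNuclei(lowNoiseSim$stack, segParams)
  counts <- vapply(c(80, 110, 140, 200, 400), function(thr) {
    p <- segmentationParams(focusThreshold = thr,
                            focusThresholdMode = "absolute")
    max(detectFoci(lowNoiseSim$stack, nuc, p))
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("noise-free rendering recovers object counts exactly", {
  # a noise-free field: rendered intensities only
  sim <- lowNoiseSim
  nuc <- detectNuclei(sim$stack, segParams)
  cel <- detectCells(sim$stack, nuc, segParams)
  foc <- detectFoci(sim$stack, nuc, segParams)
  expect_identical(max(nuc), max(labelVolume(sim$truth, "nucleus")))
  expect_identical(length(unique(cel[cel > 0L])),
                   max(labelVolume(sim$truth, "cell")))
  m <- matchObjects(foc, labelVolume(sim$truth, "focus"))
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
})

test_that("hierarchy links every focus to one nucleus and cell", {
  seg <- segmentStack(lowNoiseSim$stack, segParams)
  h <- hierarchy(seg)
  expect_identical(anyDuplicated(h$focus_id), 0L)
  expect_true(all(h$nucleus_id > 0L))
  expect_true(all(h$cell_id > 0L))
  # parent assignments equal ground-truth parentage for matched objects
  truthFoci <- groundTruthFoci(lowNoiseSim$truth)
  ovF <- SpeckleQuant:::labelOverlap(labelVolume(seg, "focus"),
                                     labelVolume(lowNoiseSim$truth, "focus"))
  ovF <- ovF[order(ovF$a, -ovF$n), ]
  bestF <- ovF[!duplicated(ovF$a), ]
  ovN <- SpeckleQuant:::labelOverlap(labelVolume(seg, "nucleus"),
                                     labelVolume(lowNoiseSim$truth,
                                                 "nucleus"))
  ovN <- ovN[order(ovN$a, -ovN$n), ]
  bestN <- ovN[!duplicated(ovN$a), ]
  checked <- 0L
  for (k in seq_len(nrow(h))) {
    truthFocus <- bestF$b[match(h$focus_id[k], bestF$a)]
    if (is.na(truthFocus)) next
    truthCellOfFocus <- truthFoci$cell_id[match(truthFocus,
                                                truthFoci$focus_id)]
    truthNucOfDetected <- bestN$b[match(h$nucleus_id[k], bestN$a)]
    expect_identical(truthNucOfDetected, truthCellOfFocus)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("trivial containment: three foci in one cell share its id", {
  shp <- c(4L, 20L, 20L)
  nuclear <- array(0, shp); nuclear[2:3, 4:16, 4:16] <- 100
  foci <- array(0, shp); foci[2:3, 4:16, 4:16] <- 50
  foci[2, 6, 6] <- 400; foci[2, 12, 12] <- 400; foci[3, 8, 14] <- 400
  stack <- voxelStack(list(nuclear, foci), c(0.5, 0.2, 0.2),
                      c("nuclear", "foci_marker"))
  p <- segmentationParams(minNucleusVolume = 0, minFocusVolume = 0)
  nuc <- detectNuclei(stack, p)
  seg <- linkHierarchy(detectCells(stack, nuc, p), nuc,
                       detectFoci(stack, nuc, p), stack)
  h <- hierarchy(seg)
  expect_identical(nrow(h), 3L)
  expect_identical(length(unique(h$cell_id)), 1L)
})

test_that("a focus straddling two nuclei goes to the majority nucleus", {
  shp <- c(1L, 5L, 10L)
  nuclear <- array(0, shp)
  nuclear[1, , 1:6] <- 100   # nucleus covering 60% of the focus column
  nuclear[1, , 7:10] <- 0
  nucLab <- array(0L, shp)
  nucLab[1, , 1:6] <- 1L
  nucLab[1, , 7:10] <- 2L    # second nucleus provided directly
  fociLab <- array(0L, shp)
  fociLab[1, 3, 1:10] <- 1L  # 6 voxels in nucleus 1, 4 in nucleus 2
  fociCh <- array(0, shp)
  fociCh[fociLab > 0L] <- 90 # uniform intensity: centroid in nucleus 1
  stack <- voxelStack(list(nuclear, fociCh), c(0.5, 0.2, 0.2),
                      c("nuclear", "foci_marker"))
  seg <- linkHierarchy(nucLab, nucLab, fociLab, stack)
  expect_identical(hierarchy(seg)$nucleus_id, 1L)
})

test_that("label volumes keep labels disjoint within each class", {
  seg <- segmentStack(lowNoiseSim$stack, segParams)
  for (w in c("cell", "nucleus", "focus")) {
    lab <- labelVolume(seg, w)
    expect_true(all(lab >= 0L))
    expect_identical(length(dim(lab)), 3L)
  }
  # nucleus voxels are a subset of the matching cell's voxels
  nuc <- labelVolume(seg, "nucleus")
  cel <- labelVolume(seg, "cell")
  expect_true(all(cel[nuc > 0L] == nuc[nuc > 0L]))
})

test_that("the anisotropic distance transform matches brute force", {
  set.seed(7)
  d <- c(5L, 6L, 7L)
  vs <- c(0.5, 0.2, 0.2)
  m <- array(runif(prod(d)) < 0.4, d)
  edt <- SpeckleQuant:::distanceTransform(m, vs)
  coords <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  pz <- coords$z * vs[1]; py <- coords$y * vs[2]; px <- coords$x * vs[3]
  bg <- which(!m)
  for (i in which(m)) {
    bf <- min(sqrt((pz[i] - pz[bg])^2 + (py[i] - py[bg])^2 +
                     (px[i] - px[bg])^2))
    expect_equal(edt[i], bf, tolerance = 1e-12)
  }
  expect_true(all(edt[!m] == 0))
})
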