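test_that("percent positive is plain division on the 0-100 scale", {
  tab <- contingencyTable(c("a", "b", "c"), c(598, 0, 158),
                          c(813, 100, 173), "a")
  pct <- percentPositive(tab)
  expect_equal(round(pct$percent, 1), c(73.6, 0.0, 91.3))
  expect_error(contingencyTable("a", 5, 0, "a"))
})

test_that("odds ratios follow the Wald formula and its symmetries", {
  tab <- contingencyTable(c("FL", "dIBB"), c(91, 144), c(166, 519), "FL")
  or <- oddsRatio(tab)
  i <- match("dIBB", or$group)
  manual <- (144 / 375) / (91 / 75)
  se <- sqrt(1 / 144 + 1 / 375 + 1 / 91 + 1 / 75)
  expect_equal(or$or[i], manual, tolerance = 1e-12)
  expect_equal(or$ci_low[i], exp(log(manual) - 1.959964 * se),
               tolerance = 1e-12)
  expect_equal(or$p_value[i], 2 * pnorm(-abs(log(manual) / se)),
               tolerance = 1e-12)
  # reciprocity: swapping reference inverts the OR and swaps/inverts the CI
  sw <- oddsRatio(contingencyTable(c("FL", "dIBB"), c(91, 144),
                                   c(166, 519), "dIBB"))
  j <- match("FL", sw$group)
  expect_equal(sw$or[j], 1 / or$or[i], tolerance = 1e-12)
  expect_equal(sw$ci_low[j], 1 / or$ci_high[i], tolerance = 1e-12)
  expect_equal(sw$ci_high[j], 1 / or$ci_low[i], tolerance = 1e-12)
  # identical groups: OR 1, CI straddles 1
  eq <- oddsRatio(contingencyTable(c("x", "y"), c(40, 40), c(100, 100),
                                   "x"))
  k <- match("y", eq$group)
  expect_equal(eq$or[k], 1)
  expect_lt(eq$ci_low[k], 1); expect_gt(eq$ci_high[k], 1)
  # zero cell: flagged non-estimable, no continuity correction
  z <- oddsRatio(contingencyTable(c("x", "y"), c(0, 40), c(100, 100), "y"))
  expect_false(z$estimable[match("x", z$group)])
  expect_true(is.na(z$or[match("x", z$group)]))
})

test_that("geometric means back-transform the log-scale mean", {
  expect_equal(geometricMeanCI(c(2, 8))$gm, 4)
  g <- geometricMeanCI(rep(3.5, 10))
  expect_equal(g$gm, 3.5)
  expect_equal(g$ci_low, 3.5)              # zero spread
  # scale equivariance: GM(kx) = k GM(x)
  set.seed(2)
  x <- rlnorm(50)
  expect_equal(geometricMeanCI(5 * x)$gm, 5 * geometricMeanCI(x)$gm,
               tolerance = 1e-12)
  # t-based interval oracle
  g2 <- geometricMeanCI(x)
  expect_equal(g2$ci_low,
               exp(mean(log(x)) - qt(0.975, 49) * sd(log(x)) / sqrt(50)),
               tolerance = 1e-12)
  expect_error(geometricMeanCI(c(1, 0, 2)), "positive")
})

test_that("GM ratios equal ratios of per-group geometric means", {
  v <- c(2, 8, 1, 4)                     # GMs 4 and 2
  g <- c("a", "a", "b", "b")
  rt <- gmRatioRegression(v, g, "a")
  expect_equal(rt$ratio[match("b", rt$group)], 0.5, tolerance = 1e-12)
  expect_equal(rt$ratio[match("a", rt$group)], 1)
  # invariance to a common scale factor
  rt2 <- gmRatioRegression(100 * v, g, "a")
  expect_equal(rt2$ratio, rt$ratio, tolerance = 1e-12)
  # ratio against itself is exactly one
  self <- gmRatioRegression(c(v, v), c(g, g), "a")
  expect_equal(self$ratio[match("a", self$group)], 1)
})

test_that("GEE with singleton clusters reduces to OLS", {
  set.seed(12)
  n <- 300
  g <- rep(c("r", "t"), each = n / 2)
  v <- exp(rnorm(n, ifelse(g == "t", log(0.8), 0), 0.5))
  gee <- geeRatio(v, cluster = seq_len(n), groups = g, reference = "r")
  ols <- gmRatioRegression(v, g, "r")
  i <- match("t", gee$group)
  expect_equal(gee$ratio[i], ols$ratio[match("t", ols$group)],
               tolerance = 1e-8)
  expect_equal(gee$alpha[1], 0)
})

test_that("GEE recovers a known clustered ratio with positive alpha", {
  d <- clusteredFociSim(ratio = 0.7, icc = 0.4, seed = 33)
  rt <- geeRatio(d$value, d$cell_id, d$group, "ref")
  i <- match("test", rt$group)
  expect_gt(rt$alpha[1], 0.2)            # exchangeable correlation found
  expect_gt(0.7, rt$ci_low[i])
  expect_lt(0.7, rt$ci_high[i])
  expect_true(rt$converged[1])
})

test_that("duplicating balanced clusters leaves the GEE estimate unchanged", {
  d <- clusteredFociSim(nCellsPerGroup = 60, fociPerCell = 4, seed = 44)
  rt1 <- geeRatio(d$value, d$cell_id, d$group, "ref")
  dd <- rbind(d, transform(d, cell_id = cell_id + 10000))
  rt2 <- geeRatio(dd$value, dd$cell_id, dd$group, "ref")
  i <- match("test", rt1$group)
  expect_equal(rt2$ratio[i], rt1$ratio[i], tolerance = 1e-8)
  # robust SE shrinks with the doubled information
  width1 <- log(rt1$ci_high[i]) - log(rt1$ci_low[i])
  width2 <- log(rt2$ci_high[i]) - log(rt2$ci_low[i])
  expect_lt(width2, width1)
})

test_that("Bonferroni threshold divides the level by the group count", {
  expect_equal(bonferroniThreshold(0.05, 6), 0.05 / 6)
  expect_equal(bonferroniThreshold(0.05, 8), 0.00625)
  expect_equal(bonferroniThreshold(0.03, 1), 0.03)
  expect_error(bonferroniThreshold(1.2, 4))
})

test_that("correlation layer matches hand values and flags degeneracy", {
  exact <- intensityFncCorrelation(
    data.frame(marker_mean = 1:10, fnc = 2 * (1:10)))
  expect_equal(exact$c, 1)
  hand <- intensityFncCorrelation(
    data.frame(marker_mean = c(1, 2, 3), fnc = c(6, 4, 5)))
  expect_equal(hand$c, -0.5)
  expect_identical(hand$n, 3L)
  flat <- intensityFncCorrelation(
    data.frame(marker_mean = rep(2, 5), fnc = rnorm(5)))
  expect_false(flat$defined)
  expect_error(intensityFncCorrelation(
    data.frame(marker_mean = 1:2, fnc = 1:2)), "at least 3")
  # spearman option
  sp <- intensityFncCorrelation(
    data.frame(marker_mean = 1:10, fnc = exp(1:10)), method = "spearman")
  expect_equal(sp$c, 1)
})

test_that("marker-coupled cohorts recover the correlation sign", {
  up <- generateCohort(cohortSpec(
    data.frame(group = "g", n = 3000L), markerFncSlope = 0.3, seed = 51L))
  dn <- generateCohort(cohortSpec(
    data.frame(group = "g", n = 3000L), markerFncSlope = -0.3, seed = 52L))
  expect_gt(intensityFncCorrelation(up$cells)$c, 0)
  expect_lt(intensityFncCorrelation(dn$cells)$c, 0)
})

test_that("covariance PCA reports scores and explained variance", {
  # two groups always lie on one axis
  two <- pcaGroupSummary(rbind(a = c(1, 5, 2), b = c(2, 9, 1)))
  expect_equal(unname(two$explained["PC1"]), 1)
  # near-rank-1 matrix: dominant first component
  set.seed(13)
  base <- c(0.5, 3, 40, 800)
  mat <- outer(c(1, 1.4, 2.1, 2.9, 3.6), base) *
    matrix(1 + rnorm(20, 0, 0.01), 5, 4)
  p <- pcaGroupSummary(mat)
  expect_gt(p$explained["PC1"], 0.99)
  expect_false(p$degenerate)
  # constant matrix is flagged degenerate with zero scores
  d <- pcaGroupSummary(matrix(3, 4, 3))
  expect_true(d$degenerate)
  expect_true(all(d$scores == 0))
})

test_that("group summary table reconciles with its inputs", {
  coh <- generateCohort(cohortSpec(
    data.frame(group = c("FL", "dIBB"), n = 400L, pi = c(0.6, 0.3),
               fnc_gm = c(2.6, 1.9)), seed = 77L))
  res <- summarizeGroups(coh$cells, coh$foci, reference = "FL")
  expect_equal(attr(res, "bonferroni_threshold"), 0.025)
  nrow_fl <- res[res$statistic == "n_cells" & res$group == "FL", "value"]
  expect_equal(nrow_fl, 400)
  pct <- res[res$statistic == "pct_foci_positive", ]
  byHand <- 100 * with(coh$cells, tapply(foci_positive, group, mean))
  expect_equal(pct$value[match(names(byHand), pct$group)],
               as.numeric(byHand), tolerance = 1e-12)
  gmf <- res[res$statistic == "gm_fnc", ]
  gmHand <- exp(with(coh$cells, tapply(log(fnc), group, mean)))
  expect_equal(gmf$value[match(names(gmHand), gmf$group)],
               as.numeric(gmHand), tolerance = 1e-12)
  # reference rows carry ratio exactly 1
  expect_true(all(res$ratio[res$group == "FL" & !is.na(res$ratio)] == 1))
  # single-group summaries stay descriptive (no ratios)
  solo <- summarizeGroups(coh$cells[coh$cells$group == "FL", ],
                          coh$foci[coh$foci$group == "FL", ],
                          reference = "FL")
  expect_true(all(is.na(solo$ratio) | solo$ratio == 1))
})
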