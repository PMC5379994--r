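#' Group-level results table
#'
#' Builds the standard group comparison: per group the analysed cell count,
#' foci count and foci-positive percentage with Wald odds ratios against the
#' reference (logistic layer); geometric means with 95\% CIs and
#' geometric-mean ratios by log-linear regression for per-cell outcomes
#' (F_n/c, whole-cell channel means over all cells; foci count, summed focus
#' volume and summed focus intensity over foci-positive cells only); and GEE
#' ratios with cell-clustered sandwich errors for per-focus outcomes (volume,
#' mean voxel intensity, summed intensity). Significance is flagged at the
#' Bonferroni-adjusted threshold \code{alpha / bonferroniDivisor}.
#'
#' @param cells per-cell table (see \code{\link{buildCellTable}} /
#'   \code{\link{generateCohort}}); needs \code{group}, \code{foci_positive},
#'   \code{foci_count}, \code{sum_foci_volume}, \code{sum_foci_intensity} and
#'   at least one of \code{F_n_over_c} / \code{fnc}.
#' @param foci per-focus table with \code{cell_id}, \code{group},
#'   \code{volume_um3}, \code{mean_intensity}, \code{sum_intensity}.
#' @param reference reference group for all ratios.
#' @param alpha nominal significance level.
#' @param bonferroniDivisor divisor for the adjusted threshold; defaults to
#'   the number of groups.
#' @param countMode count outcomes over foci-positive cells only (default) or
#'   over all cells after adding one (\code{"include_zeroes"}).
#' @param geeCorstr working correlation for the per-focus GEE.
#' @return A long-format data.frame: \code{statistic}, \code{group},
#'   \code{n}, \code{value} (count, percentage or GM), \code{ci_low},
#'   \code{ci_high}, \code{ratio}, \code{ratio_ci_low}, \code{ratio_ci_high},
#'   \code{p_value}, \code{significant}; attribute
#'   \code{"bonferroni_threshold"}.
#' @examples
#' coh <- generateCohort(cohortSpec(data.frame(group = c("FL", "dIBB"),
#'                                             n = 200, pi = c(0.6, 0.3))))
#' res <- summarizeGroups(coh$cells, coh$foci, reference = "FL")
#' head(res)
#' @export
summarizeGroups <- function(cells, foci, reference, alpha = 0.05,
                            bonferroniDivisor = NULL,
                            countMode = c("positive_only", "include_zeroes"),
                            geeCorstr = "exchangeable") {
  countMode <- match.arg(countMode)
  grps <- unique(cells$group)
  stopifnot(reference %in% grps)
  if (is.null(bonferroniDivisor)) bonferroniDivisor <- length(grps)
  thr <- bonferroniThreshold(alpha, bonferroniDivisor)
  fncCol <- if ("F_n_over_c" %in% names(cells)) "F_n_over_c" else "fnc"

  rows <- list()
  addRow <- function(statistic, group, n, value, ci_low = NA, ci_high = NA,
                     ratio = NA, rlo = NA, rhi = NA, p = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, group = group, n = n, value = value,
      ci_low = ci_low, ci_high = ci_high, ratio = ratio,
      ratio_ci_low = rlo, ratio_ci_high = rhi, p_value = p,
      significant = !is.na(p) & p <= thr)
  }

  # contingency layer
  pos <- vapply(grps, function(g)
    sum(cells$foci_positive[cells$group == g]), 0L)
  tot <- vapply(grps, function(g) sum(cells$group == g), 0L)
  tab <- contingencyTable(grps, pos, tot, reference)
  pct <- percentPositive(tab)
  ors <- oddsRatio(tab)
  nFociPerGroup <- if (nrow(foci))
    vapply(grps, function(g) sum(foci$group == g, na.rm = TRUE), 0L)
  else rep(0L, length(grps))
  for (i in seq_along(grps)) {
    addRow("n_cells", grps[i], tot[i], tot[i])
    addRow("n_foci", grps[i], tot[i], nFociPerGroup[i])
    addRow("n_foci_positive", grps[i], tot[i], pos[i])
    addRow("pct_foci_positive", grps[i], tot[i], pct$percent[i],
           ratio = ors$or[i], rlo = ors$ci_low[i], rhi = ors$ci_high[i],
           p = ors$p_value[i])
  }

  # per-cell continuous outcomes over all cells
  perCellAll <- c(fnc = fncCol,
                  mean_foci_marker = "mean_foci_marker",
                  mean_cell_marker = "mean_cell_marker")
  perCellAll <- perCellAll[perCellAll %in% names(cells)]
  for (nm in names(perCellAll)) {
    v <- cells[[perCellAll[[nm]]]]
    ok <- is.finite(v) & v > 0
    .gmStat(addRow, paste0("gm_", nm), cells$group[ok], v[ok], reference)
  }

  # per-cell foci outcomes, foci-positive cells only (or shifted counts)
  posCells <- cells[cells$foci_positive, , drop = FALSE]
  if (countMode == "positive_only") {
    if (nrow(posCells))
      .gmStat(addRow, "gm_foci_count", posCells$group,
              posCells$foci_count, reference)
  } else {
    .gmStat(addRow, "gm_foci_count_plus1", cells$group,
            cells$foci_count + 1, reference)
  }
  for (nm in c("sum_foci_volume", "sum_foci_intensity")) {
    if (!nrow(posCells)) break
    v <- posCells[[nm]]
    ok <- is.finite(v) & v > 0
    .gmStat(addRow, paste0("gm_", nm), posCells$group[ok], v[ok], reference)
  }

  # per-focus outcomes with GEE
  if (nrow(foci)) {
    for (nm in c("volume_um3", "mean_intensity", "sum_intensity")) {
      v <- foci[[nm]]
      ok <- is.finite(v) & v > 0 & !is.na(foci$cell_id)
      if (length(unique(foci$group[ok])) < 2L) next
      gm <- lapply(split(v[ok], foci$group[ok]), geometricMeanCI)
      rt <- geeRatio(v[ok], foci$cell_id[ok], foci$group[ok], reference,
                     corstr = geeCorstr)
      for (g in names(gm))
        addRow(paste0("gm_focus_", nm), g, gm[[g]]$n, gm[[g]]$gm,
               gm[[g]]$ci_low, gm[[g]]$ci_high,
               ratio = rt$ratio[match(g, rt$group)],
               rlo = rt$ci_low[match(g, rt$group)],
               rhi = rt$ci_high[match(g, rt$group)],
               p = rt$p_value[match(g, rt$group)])
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "reference") <- reference
  out
}

# GM + CI per group and GM ratios vs the reference for one outcome.
.gmStat <- function(addRow, statistic, groups, values, reference) {
  if (!length(values)) return(invisible())
  gm <- lapply(split(values, groups), geometricMeanCI)
  rt <- if (length(unique(groups)) >= 2L && reference %in% groups)
    gmRatioRegression(values, groups, reference) else NULL
  for (g in names(gm)) {
    i <- if (!is.null(rt)) match(g, rt$group) else NA_integer_
    addRow(statistic, g, gm[[g]]$n, gm[[g]]$gm, gm[[g]]$ci_low,
           gm[[g]]$ci_high,
           ratio = if (!is.null(rt) && !is.na(i)) rt$ratio[i] else NA,
           rlo = if (!is.null(rt) && !is.na(i)) rt$ci_low[i] else NA,
           rhi = if (!is.null(rt) && !is.na(i)) rt$ci_high[i] else NA,
           p = if (!is.null(rt) && !is.na(i)) rt$p_value[i] else NA)
  }
  invisible()
}

#' PCA summary of a group results table
#'
#' Pivots the long results of \code{\link{summarizeGroups}} into a
#' groups-by-parameters matrix of geometric means / percentages and runs
#' \code{\link{pcaGroupSummary}}.
#'
#' @param results output of \code{\link{summarizeGroups}}.
#' @param statistics which statistics to use as parameters (default: all GM
#'   statistics plus the positive percentage).
#' @param scale standardise columns.
#' @return See \code{\link{pcaGroupSummary}}.
#' @examples
#' coh <- generateCohort(cohortSpec(data.frame(
#'   group = c("a", "b", "c"), n = 150, pi = c(.7, .5, .3))))
#' res <- summarizeGroups(coh$cells, coh$foci, reference = "a")
#' resultsPca(res)$explained
#' @export
resultsPca <- function(results, statistics = NULL, scale = FALSE) {
  if (is.null(statistics))
    statistics <- unique(results$statistic[
      grepl("^gm_|^pct_", results$statistic)])
  sub <- results[results$statistic %in% statistics, ]
  grps <- unique(sub$group)
  mat <- matrix(NA_real_, length(grps), length(statistics),
                dimnames = list(grps, statistics))
  for (k in seq_len(nrow(sub)))
    mat[sub$group[k], sub$statistic[k]] <- sub$value[k]
  keep <- colSums(is.na(mat)) == 0L
  pcaGroupSummary(mat[, keep, drop = FALSE], scale = scale)
}
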