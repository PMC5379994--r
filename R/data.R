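#' Published foci-positivity counts from IMPa modulation experiments
#'
#' Per-group cell counts from three HeLa transfection experiments in which
#' GFP-tagged importin-alpha (IMPa2/4/6) variants — full length (FL),
#' transport-dead truncations (dIBB) and a cargo-binding-dead control (ED) —
#' were scored for the presence of nuclear foci marked by endogenous PSPC1,
#' endogenous SFPQ or co-transfected DsRed2-PSPC1. Columns:
#' \code{marker}, \code{group}, \code{cells_total} (cells analysed),
#' \code{cells_positive} (cells with at least one nuclear focus),
#' \code{foci_total} (foci detected in the group), and
#' \code{reference_group} (the full-length isoform each group is compared
#' against). These counts are the inputs to the contingency layer
#' (\code{\link{percentPositive}}, \code{\link{oddsRatio}}).
#'
#' @return data.frame with 22 rows.
#' @examples
#' counts <- impaFociCounts()
#' subset(counts, marker == "PSPC1")
#' @export
impaFociCounts <- function() {
  read.csv(system.file("extdata", "impa_foci_counts.csv",
                       package = "SpeckleQuant"))
}
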