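.Z975 <- 1.959964  # two-sided 95% normal quantile used for Wald intervals

#' Build a foci-positivity contingency table
#'
#' @param group character vector of group names.
#' @param positives integer, foci-positive cells per group.
#' @param totals integer, cells analysed per group.
#' @param reference name of the reference group (odds ratios are reported
#'   against it).
#' @return data.frame with class \code{"contingency_table"} and attribute
#'   \code{"reference"}.
#' @examples
#' contingencyTable(c("FL", "dIBB"), c(91, 144), c(166, 519), "FL")
#' @export
contingencyTable <- function(group, positives, totals, reference) {
  stopifnot(length(group) == length(positives),
            length(group) == length(totals),
            all(totals > 0), all(positives >= 0), all(positives <= totals),
            reference %in% group)
  out <- data.frame(group = as.character(group),
                    positives = as.integer(positives),
                    totals = as.integer(totals))
  attr(out, "reference") <- reference
  class(out) <- c("contingency_table", "data.frame")
  out
}

#' Percentage of foci-positive cells per group
#'
#' @param tab a \code{\link{contingencyTable}}.
#' @return data.frame: \code{group}, \code{percent} (0-100 scale; report to
#'   one decimal).
#' @examples
#' percentPositive(contingencyTable("GFP", 598, 813, "GFP"))
#' @export
percentPositive <- function(tab) {
  data.frame(group = tab$group, percent = 100 * tab$positives / tab$totals)
}

#' Wald odds ratios for foci positivity
#'
#' For each non-reference group, the odds ratio against the reference with a
#' Wald 95\% confidence interval,
#' \eqn{\exp(\ln OR \pm 1.959964 \sqrt{\sum 1/n_{ij}})}, and a two-sided Wald
#' p-value. These are the estimates a logistic regression of positivity on
#' group indicators produces for a saturated two-group comparison. A zero
#' cell makes the OR non-estimable; it is flagged (\code{estimable = FALSE})
#' rather than continuity-corrected.
#'
#' @param tab a \code{\link{contingencyTable}}.
#' @return data.frame: \code{group}, \code{reference}, \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{estimable}; the
#'   reference row carries \code{or = 1}.
#' @examples
#' oddsRatio(contingencyTable(c("FL", "dIBB"), c(91, 144), c(166, 519),
#'                            "FL"))
#' @export
oddsRatio <- function(tab) {
  ref <- attr(tab, "reference")
  i0 <- match(ref, tab$group)
  a0 <- tab$positives[i0]
  b0 <- tab$totals[i0] - a0
  out <- data.frame(group = tab$group, reference = ref, or = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, estimable = TRUE)
  for (i in seq_len(nrow(tab))) {
    if (i == i0) { out$or[i] <- 1; next }
    a1 <- tab$positives[i]
    b1 <- tab$totals[i] - a1
    if (min(a1, b1, a0, b0) == 0) { out$estimable[i] <- FALSE; next }
    lor <- log((a1 / b1) / (a0 / b0))
    se <- sqrt(1 / a1 + 1 / b1 + 1 / a0 + 1 / b0)
    out$or[i] <- exp(lor)
    out$ci_low[i] <- exp(lor - .Z975 * se)
    out$ci_high[i] <- exp(lor + .Z975 * se)
    out$p_value[i] <- 2 * pnorm(-abs(lor / se))
  }
  out
}

#' Geometric mean with a 95\% confidence interval
#'
#' Values are transformed with the natural logarithm; the mean of the logs is
#' back-transformed to the geometric mean, and the interval is
#' \eqn{\exp(\bar{x} \pm t_{0.975, n-1} \cdot SE)} (t distribution, n - 1
#' degrees of freedom). Zeros and negatives are a caller error: outcomes with
#' zeros are defined over foci-positive cells upstream.
#'
#' @param values positive numeric vector.
#' @return A list: \code{gm}, \code{ci_low}, \code{ci_high}, \code{n}
#'   (\code{ci_*} are \code{NA} for n < 2).
#' @examples
#' geometricMeanCI(c(2, 8))$gm  # 4
#' @export
geometricMeanCI <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("geometric mean requires positive values; offending record(s): ",
         paste(head(bad, 5L), collapse = ", "))
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  if (n < 2L)
    return(list(gm = exp(m), ci_low = NA_real_, ci_high = NA_real_, n = n))
  se <- sd(lx) / sqrt(n)
  tq <- qt(0.975, n - 1L)
  list(gm = exp(m), ci_low = exp(m - tq * se), ci_high = exp(m + tq * se),
       n = n)
}

#' Geometric-mean ratios by log-linear regression
#'
#' Ordinary least squares of \eqn{\ln(value)} on group indicators with the
#' reference group as baseline. Exponentiated coefficients are the ratios of
#' geometric means; intervals are exponentiated Wald intervals and p-values
#' come from the coefficient t-tests.
#'
#' @param values positive numeric outcomes.
#' @param groups group labels (same length).
#' @param reference reference group name.
#' @return data.frame: \code{group}, \code{reference}, \code{ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{n}; the reference
#'   row carries \code{ratio = 1}.
#' @examples
#' gmRatioRegression(c(2, 8, 1, 4), c("a", "a", "b", "b"), "a")
#' @export
gmRatioRegression <- function(values, groups, reference) {
  stopifnot(length(values) == length(groups), reference %in% groups)
  if (any(!is.finite(values) | values <= 0))
    stop("log-linear regression requires positive values")
  g <- stats::relevel(factor(groups), ref = reference)
  fit <- lm(log(values) ~ g)
  sm <- summary(fit)$coefficients
  lev <- levels(g)
  out <- data.frame(group = lev, reference = reference, ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_,
                    n = as.integer(table(g)[lev]))
  out$ratio[1] <- 1
  for (k in seq_along(lev)[-1]) {
    nm <- paste0("g", lev[k])
    if (!nm %in% rownames(sm) || is.na(sm[nm, 2])) next
    est <- sm[nm, 1]
    se <- sm[nm, 2]
    out$ratio[k] <- exp(est)
    out$ci_low[k] <- exp(est - .Z975 * se)
    out$ci_high[k] <- exp(est + .Z975 * se)
    out$p_value[k] <- sm[nm, 4]
  }
  out
}

# Gaussian identity-link GEE on a fixed design matrix.
# Exchangeable (or independence) working correlation, moment estimates of
# scale and correlation, robust sandwich covariance. Clusters enter through
# the closed-form inverse of V = phi * ((1 - alpha) I + alpha J).
.geeFit <- function(y, X, cluster, corstr = "exchangeable",
                    maxit = 50L, tol = 1e-10) {
  cl <- split(seq_along(y), cluster)
  p <- ncol(X)
  beta <- qr.solve(X, y)
  alpha <- 0
  nPairs <- sum(vapply(cl, function(i) {
    ni <- length(i); ni * (ni - 1) / 2
  }, 0))
  for (iter in seq_len(maxit)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable" && nPairs > p) {
      num <- sum(vapply(cl, function(i) {
        ri <- r[i]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, 0))
      alpha <- num / ((nPairs - p) * phi)
      alpha <- max(min(alpha, 0.99), -0.99)
    } else alpha <- 0
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (i in cl) {
      ni <- length(i)
      Xi <- X[i, , drop = FALSE]
      yi <- y[i]
      # V^{-1} x = (x - c * sum(x) * 1) / (1 - alpha), c = alpha/(1+(ni-1)a)
      cc <- alpha / (1 + (ni - 1) * alpha)
      ViX <- (Xi - cc * matrix(colSums(Xi), ni, p, byrow = TRUE)) /
        (1 - alpha)
      A <- A + crossprod(Xi, ViX)
      Viy <- (yi - cc * sum(yi)) / (1 - alpha)
      b <- b + crossprod(Xi, Viy)
    }
    betaNew <- solve(A, b)
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < tol) break
  }
  converged <- delta < tol
  # sandwich
  r <- as.numeric(y - X %*% beta)
  M <- matrix(0, p, p)
  for (i in cl) {
    ni <- length(i)
    Xi <- X[i, , drop = FALSE]
    cc <- alpha / (1 + (ni - 1) * alpha)
    ViX <- (Xi - cc * matrix(colSums(Xi), ni, p, byrow = TRUE)) / (1 - alpha)
    u <- crossprod(ViX, r[i])
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  vcov <- Ainv %*% M %*% Ainv
  vcov <- (vcov + t(vcov)) / 2
  # guard against non-estimable variances in tiny designs
  diag(vcov)[diag(vcov) < 0] <- NA_real_
  list(beta = as.numeric(beta), vcov = vcov, alpha = alpha, phi = phi,
       iterations = iter, converged = converged,
       n_clusters = length(cl))
}

#' GEE geometric-mean ratios for per-focus outcomes
#'
#' Per-focus values (volumes, intensities) from the same cell are correlated,
#' so group ratios are estimated by generalized estimating equations with an
#' identity link on \eqn{\ln(value)}, an exchangeable working correlation
#' (independence available as an option) and robust (sandwich) standard
#' errors clustered on the parent cell. Exponentiated coefficients are the
#' geometric-mean ratios. When every cluster has size one the estimates
#' reduce to the ordinary log-linear regression.
#'
#' @param values positive per-focus outcomes.
#' @param cluster parent-cell identifiers (one per focus).
#' @param groups group labels (one per focus).
#' @param reference reference group name.
#' @param corstr working correlation structure.
#' @return data.frame as in \code{\link{gmRatioRegression}} plus columns
#'   \code{n_clusters}, \code{alpha} (estimated working correlation),
#'   \code{converged} and \code{flagged} (group with fewer than 2 clusters).
#' @examples
#' geeRatio(c(1, 2, 2, 4), c(1, 1, 2, 2), c("a", "a", "b", "b"), "a")
#' @export
geeRatio <- function(values, cluster, groups, reference,
                     corstr = c("exchangeable", "independence")) {
  corstr <- match.arg(corstr)
  stopifnot(length(values) == length(cluster),
            length(values) == length(groups), reference %in% groups)
  if (any(!is.finite(values) | values <= 0))
    stop("GEE ratio analysis requires positive values")
  g <- stats::relevel(factor(groups), ref = reference)
  X <- model.matrix(~g)
  fit <- .geeFit(log(values), X, as.character(cluster), corstr)
  if (!fit$converged)
    warning("GEE did not converge in ", fit$iterations, " iterations")
  lev <- levels(g)
  clPerGroup <- vapply(lev, function(l)
    length(unique(cluster[groups == l])), 0L)
  out <- data.frame(group = lev, reference = reference, ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_,
                    n = as.integer(table(g)[lev]),
                    n_clusters = as.integer(clPerGroup),
                    alpha = fit$alpha, converged = fit$converged,
                    flagged = clPerGroup < 2L)
  out$ratio[1] <- 1
  se <- sqrt(diag(fit$vcov))
  for (k in seq_along(lev)[-1]) {
    est <- fit$beta[k]
    out$ratio[k] <- exp(est)
    out$ci_low[k] <- exp(est - .Z975 * se[k])
    out$ci_high[k] <- exp(est + .Z975 * se[k])
    out$p_value[k] <- 2 * pnorm(-abs(est / se[k]))
  }
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' The nominal level divided by the number of experimental groups in the
#' experiment (the divisor used in the group tables: 6 or 8 groups give
#' reported thresholds of 0.008 and 0.0063 respectively).
#'
#' @param alpha nominal level in (0, 1).
#' @param kGroups number of experimental groups (>= 1).
#' @return \code{alpha / kGroups}, exact (format for reporting separately).
#' @examples
#' bonferroniThreshold(0.05, 8)
#' @export
bonferroniThreshold <- function(alpha, kGroups) {
  stopifnot(alpha > 0, alpha < 1, kGroups >= 1)
  alpha / kGroups
}

#' Correlation between per-cell marker intensity and F_n/c
#'
#' Pearson (default) or Spearman correlation between the per-cell mean
#' importin-marker intensity and the per-cell F_n/c, pooled across treatment
#' groups. Requires at least 3 cells with a defined ratio; zero variance in
#' either variable is flagged as undefined.
#'
#' @param cells per-cell data.frame.
#' @param intensityCol name of the marker-intensity column.
#' @param fncCol name of the F_n/c column.
#' @param method correlation type.
#' @return A list: \code{n}, \code{c} (coefficient, \code{NA} if undefined),
#'   \code{method}, \code{defined}.
#' @examples
#' intensityFncCorrelation(data.frame(marker_mean = 1:5, fnc = c(1, 3, 2, 5,
#'                                                               4)))
#' @export
intensityFncCorrelation <- function(cells, intensityCol = "marker_mean",
                                    fncCol = "fnc",
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- cells[[intensityCol]]
  y <- cells[[fncCol]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 cells with defined values")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(n = length(x), c = NA_real_, method = method,
                defined = FALSE))
  list(n = length(x), c = cor(x, y, method = method), method = method,
       defined = TRUE)
}

#' PCA summary of group geometric means
#'
#' Principal components of the groups-by-parameters matrix of geometric
#' means. Columns are centred but (by default) not standardised: on raw
#' parameter columns with heterogeneous magnitudes (intensity sums dwarf
#' ratios) the first component then typically explains >99\% of the
#' variance. Correlation-mode PCA (\code{scale = TRUE}) is available.
#'
#' @param mat numeric matrix, groups in rows, parameters in columns; no
#'   missing entries.
#' @param scale standardise columns (correlation-mode PCA).
#' @return A list: \code{scores} (groups on PC1/PC2),
#'   \code{explained} (variance fractions), \code{loadings}, \code{degenerate}
#'   (constant input).
#' @examples
#' m <- rbind(a = c(1, 10), b = c(2, 20), c = c(3, 31))
#' pcaGroupSummary(m)$explained
#' @export
pcaGroupSummary <- function(mat, scale = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 2L,
            !anyNA(mat))
  if (all(apply(mat, 2L, function(v) diff(range(v)) == 0))) {
    sc <- matrix(0, nrow(mat), 2L,
                 dimnames = list(rownames(mat), c("PC1", "PC2")))
    return(list(scores = sc, explained = c(PC1 = 0, PC2 = 0),
                loadings = NULL, degenerate = TRUE))
  }
  pc <- prcomp(mat, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) scores <- cbind(scores, PC2 = 0)
  expl <- ev / sum(ev)
  expl2 <- c(PC1 = expl[1], PC2 = if (length(expl) > 1L) expl[2] else 0)
  list(scores = scores, explained = expl2,
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       degenerate = FALSE)
}
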