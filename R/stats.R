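# The differential co-expression statistic: within-group Pearson
# correlations are Fisher z-transformed (signed arctanh) and the absolute
# difference is standardized by sqrt(1/(m1-3) + 1/(m2-3)), the asymptotic
# standard deviation of a difference of independent z-transformed
# correlations. Under the null of equal population correlation the statistic
# is approximately standard normal, giving a two-sided p-value.

R_CLAMP <- 1 - 1e-15

#' Pearson correlation of two expression vectors
#'
#' Thin validated wrapper over [stats::cor()]: covariance over the product
#' of standard deviations (the ratio is divisor-convention invariant).
#' Constant input is a degenerate-correlation error rather than `NA`, so
#' callers skip the trio explicitly.
#'
#' @param x,y numeric vectors of equal length at least 2, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("correlation requires at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate correlation: constant input vector")
  }
  stats::cor(x, y)
}

#' Fisher r-to-z transform
#'
#' `arctanh(r) = log((1 + r) / (1 - r)) / 2`, the variance-stabilizing
#' transform of a Pearson correlation. Signed: `fisher_z(-r) == -fisher_z(r)`,
#' so oppositely-signed correlations of equal magnitude remain
#' distinguishable.
#'
#' @param r correlation with `|r| < 1`.
#' @return The transformed value.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Differential-correlation z-test for two genotype groups
#'
#' Computes `Z = |atanh(r1) - atanh(r2)| / sqrt(1/(m1-3) + 1/(m2-3))` and
#' the two-sided p-value `2 * (1 - pnorm(Z))` under the standard-normal
#' approximation for the difference of independent z-transformed
#' correlations. Correlations with `|r| >= 1` (possible at small group
#' sizes) are clamped to `1 - 1e-15` in magnitude and flagged. Vectorized
#' over `r1` and `r2`.
#'
#' @param r1,r2 within-group Pearson correlations.
#' @param m1,m2 group sample sizes; each must be at least
#'   `max(4, min_group_size)` for the variance term to be positive.
#' @param min_group_size minimum acceptable group size (default 4, the hard
#'   mathematical floor; raise for stability at noisy small groups).
#' @return A data frame with columns `r1`, `r2`, `z1`, `z2`, `Z`, `p`, `m1`,
#'   `m2`, `clamped`. `Z` is symmetric in the two groups and `p` is in
#'   `(0, 1]`.
#' @export
z_statistic <- function(r1, m1, r2, m2, min_group_size = 4L) {
  mgs <- max(4L, as.integer(min_group_size))
  if (m1 < mgs || m2 < mgs) {
    stop("insufficient samples: group sizes ", m1, ", ", m2,
         " below minimum ", mgs)
  }
  clamped <- abs(r1) >= 1 | abs(r2) >= 1
  r1c <- pmin(pmax(r1, -R_CLAMP), R_CLAMP)
  r2c <- pmin(pmax(r2, -R_CLAMP), R_CLAMP)
  z1 <- atanh(r1c)
  z2 <- atanh(r2c)
  se <- sqrt(1 / (m1 - 3) + 1 / (m2 - 3))
  z <- abs(z1 - z2) / se
  p <- pmax(2 * stats::pnorm(z, lower.tail = FALSE), .Machine$double.xmin)
  data.frame(r1 = r1, r2 = r2, z1 = z1, z2 = z2, Z = z, p = pmin(p, 1),
             m1 = m1, m2 = m2, clamped = clamped)
}

#' Bonferroni threshold over the full trio family
#'
#' Family-wise threshold `alpha / (n_snps * n_probes * (n_probes - 1) / 2)`,
#' dividing by the designed number of SNP x probe-pair tests. With one SNP
#' this is the per-variant corrected threshold.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_snps number of SNPs tested.
#' @param n_probes number of expression probes (at least 2).
#' @return The per-test p-value threshold.
#' @export
bonferroni_threshold <- function(alpha, n_snps, n_probes) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_probes >= 2)
  alpha / (n_snps * n_probes * (n_probes - 1) / 2)
}

#' Benjamini-Hochberg step-up significance calls
#'
#' Standard BH step-up over the supplied p-values at FDR level `q`, the
#' less stringent alternative to the Bonferroni family-wise correction.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q target false discovery rate in (0, 1).
#' @return Logical vector marking significant entries (empty for empty
#'   input).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}
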