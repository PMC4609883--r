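# Preprocessing filters applied before a scan: minor-allele-frequency window
# on SNPs, per-transcript rank-based inverse-normal quantile normalization,
# and a top-N variance filter on probes.

#' Minor allele frequency of one SNP
#'
#' Frequency of the designated minor allele among non-missing calls:
#' (sum of minor-allele copies) / (2 x non-missing count).
#'
#' @param calls vector of genotype codes in `{0, 1, 2, NA}`.
#' @return A value in `[0, 0.5]` when the minor designation is consistent.
#' @export
minor_allele_frequency <- function(calls) {
  nm <- calls[!is.na(calls)]
  if (length(nm) == 0) stop("MAF undefined: all calls missing")
  sum(nm) / (2 * length(nm))
}

#' Filter SNPs by allele-frequency window
#'
#' Keeps SNPs whose minor-allele frequency `f` satisfies `low <= f` and
#' `1 - f <= high` (inclusive bounds). With minor-allele coding and the
#' conventional symmetric window (`high = 1 - low`) the second condition is
#' implied by the first; both are checked so asymmetric windows behave as
#' stated. SNPs with every call missing are removed with a warning.
#'
#' @param g a [genotype_matrix].
#' @param low,high allele-frequency bounds, `0 <= low <= high <= 1`. The
#'   defaults retain common variants with MAF of at least 0.2.
#' @return The filtered [genotype_matrix].
#' @export
filter_snps_by_maf <- function(g, low = 0.2, high = 0.8) {
  stopifnot(low >= 0, high <= 1, low <= high)
  all_missing <- apply(g$calls, 1, function(x) all(is.na(x)))
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) with all calls missing removed")
  }
  f <- rep(NA_real_, nrow(g$calls))
  f[!all_missing] <- apply(g$calls[!all_missing, , drop = FALSE], 1,
                           minor_allele_frequency)
  keep <- !all_missing & f >= low & (1 - f) <= high
  genotype_matrix(g$calls[keep, , drop = FALSE],
                  g$snp_info[keep, , drop = FALSE],
                  g$sample_ids)
}

#' Rank-based inverse-normal transform of one transcript
#'
#' Maps the value at ascending rank k (of n) to `qnorm((k - 0.5) / n)`,
#' preserving the input ordering. Ties receive average ranks before the
#' transform, so tied intensities map to a common value; a constant vector
#' maps to all zeros (every rank is the mid-rank). Because the transform
#' depends only on ranks, any strictly monotone rescaling of the input
#' leaves the output unchanged, and re-applying the transform is idempotent.
#'
#' @param values numeric vector with no missing entries, length at least 2.
#' @return Numeric vector of the same length with approximately standard
#'   normal margins.
#' @export
quantile_normalize_transcript <- function(values) {
  n <- length(values)
  if (n < 2) stop("quantile normalization requires n >= 2")
  if (anyNA(values)) stop("missing values not allowed")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

#' Quantile-normalize every transcript of an expression matrix
#'
#' Applies [quantile_normalize_transcript()] row-wise, the standard
#' per-transcript normalization used before differential co-expression
#' scanning (it also absorbs broad ancestry/batch scale differences).
#'
#' @param e an [expression_matrix].
#' @return An [expression_matrix] of the same shape.
#' @export
quantile_normalize <- function(e) {
  values <- t(apply(e$values, 1, quantile_normalize_transcript))
  expression_matrix(values, e$probe_ids, e$sample_ids)
}

#' Keep the top-N probes by sample variance
#'
#' Ranks probes by unbiased sample variance (divisor n - 1) and keeps the
#' `top_n` most variable; exact variance ties at the cutoff are broken by
#' probe-id lexicographic order, so the selected set is deterministic and
#' invariant to probe row order. Selected probes keep their input row order.
#' In the standard pipeline this filter runs after quantile normalization.
#'
#' @param e an [expression_matrix].
#' @param top_n number of probes to keep, at most `nrow(e$values)`.
#' @return The filtered [expression_matrix].
#' @export
variance_filter <- function(e, top_n) {
  t_probes <- nrow(e$values)
  if (top_n > t_probes) {
    stop("top_n (", top_n, ") exceeds probe count (", t_probes, ")")
  }
  v <- apply(e$values, 1, stats::var)
  ord <- order(-v, e$probe_ids, method = "radix")
  chosen <- e$probe_ids[ord[seq_len(top_n)]]
  keep <- e$probe_ids %in% chosen
  expression_matrix(e$values[keep, , drop = FALSE],
                    e$probe_ids[keep], e$sample_ids)
}
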