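# Empirical type-I-error estimation: permute genotypes while fixing
# expression, rerun the scan, and count survivors at the configured
# threshold. The default permutes each SNP's call vector independently
# across samples (destroying genotype LD, matching the published protocol);
# a sample-level alternative permutes one shared sample order for all SNPs,
# preserving LD.

# Deterministic per-SNP seed derived from the master seed and the SNP id
# (polynomial rolling hash), so each SNP's permutation stream is independent
# of iteration order.
snp_stream_seed <- function(master_seed, snp_id) {
  h <- 0
  for (ch in utf8ToInt(snp_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(h), as.integer(master_seed %% 2147483647)))
}

with_preserved_rng <- function(code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Permute genotypes across samples
#'
#' For each SNP independently (the default), the full call vector including
#' missing entries is uniformly permuted across samples, preserving every
#' per-SNP genotype count — and hence every MAF — exactly. The same master
#' seed always yields the same permutation regardless of SNP order. With
#' `per_snp = FALSE` a single sample permutation is applied to all SNPs,
#' preserving between-SNP LD structure.
#'
#' @param g a [genotype_matrix].
#' @param seed integer master seed.
#' @param per_snp permute each SNP independently (default `TRUE`).
#' @return A [genotype_matrix] with permuted calls. The caller's RNG state
#'   is left untouched.
#' @export
permute_genotypes <- function(g, seed, per_snp = TRUE) {
  n <- ncol(g$calls)
  calls <- g$calls
  with_preserved_rng({
    if (per_snp) {
      for (k in seq_len(nrow(calls))) {
        set.seed(snp_stream_seed(seed, g$snp_info$snp_id[k]))
        calls[k, ] <- calls[k, sample.int(n)]
      }
    } else {
      set.seed(as.integer(seed %% 2147483647))
      perm <- sample.int(n)
      calls <- calls[, perm, drop = FALSE]
    }
  })
  genotype_matrix(calls, g$snp_info, g$sample_ids)
}

#' Estimate the false positive rate by genotype permutation
#'
#' Permutes the genotypes (expression fixed), reruns the full scan under
#' `cfg`, and reports how many trios survive the configured threshold. Under
#' a correctly calibrated test with a Bonferroni threshold of
#' `alpha / n_tests`, the expected survivor count per whole-scan replicate
#' is approximately `alpha`.
#'
#' @param g a [genotype_matrix], sample-aligned with `e`.
#' @param e an [expression_matrix].
#' @param cfg a [scan_config()].
#' @param seed integer seed for the permutation.
#' @return A list: `n_significant`, `n_tests` (trios actually evaluated),
#'   `n_designed` (full trio count), `fpr` (survivors / evaluated), and
#'   `threshold`.
#' @export
estimate_fpr <- function(g, e, cfg = scan_config(), seed = 1L) {
  gp <- permute_genotypes(g, seed)
  scan <- run_scan(gp, e, cfg)
  s <- scan$summary
  list(
    n_significant = s$n_significant,
    n_tests = s$n_evaluated,
    n_designed = s$n_trios,
    fpr = if (s$n_evaluated > 0) s$n_significant / s$n_evaluated else NA_real_,
    threshold = s$threshold
  )
}

#' Replicated permutation null summary
#'
#' Runs [estimate_fpr()] over `n_reps` independent permutation replicates
#' (seeds `seed, seed + 1, ...`) and returns one row per replicate, the form
#' consumed by the command-line `permute` subcommand.
#'
#' @inheritParams estimate_fpr
#' @param n_reps number of permutation replicates.
#' @return Data frame with columns `replicate`, `n_tests`, `n_significant`,
#'   `threshold`.
#' @export
permutation_null <- function(g, e, cfg = scan_config(), seed = 1L,
                             n_reps = 10L) {
  rows <- lapply(seq_len(n_reps), function(i) {
    est <- estimate_fpr(g, e, cfg, seed = seed + i - 1L)
    data.frame(replicate = i, n_tests = est$n_tests,
               n_significant = est$n_significant,
               threshold = est$threshold)
  })
  do.call(rbind, rows)
}
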