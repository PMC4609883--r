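#' @keywords internal
"_PACKAGE"

# Genotype codes count copies of the designated minor allele: 0, 1, 2, or NA
# (missing). The minor designation is enforced at construction: frequency of
# the allele coded as minor among non-missing calls must be <= 0.5.

MISSING_ALLELES <- c("0", "N")

#' Construct a genotype matrix
#'
#' In-memory container for biallelic genotype calls: an S x N integer matrix
#' of minor-allele copy counts (0, 1, 2) with `NA` marking missing calls,
#' plus per-SNP annotation (chromosome, 1-based position, major/minor allele
#' characters). Positions are carried as annotation only and never enter any
#' computation.
#'
#' @param calls integer matrix, SNPs in rows, samples in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param snp_info data frame with columns `snp_id`, `chrom`, `pos`,
#'   `major`, `minor` (allele characters; `minor` may be `NA` for a
#'   monomorphic SNP), one row per SNP.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `snp_info`, `sample_ids`.
#' @export
genotype_matrix <- function(calls, snp_info, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  required <- c("snp_id", "chrom", "pos", "major", "minor")
  if (!all(required %in% names(snp_info))) {
    stop("snp_info must have columns: ", paste(required, collapse = ", "))
  }
  snp_info <- as.data.frame(snp_info)[required]
  if (nrow(snp_info) != nrow(calls)) {
    stop("snp_info rows (", nrow(snp_info), ") != calls rows (", nrow(calls), ")")
  }
  if (length(sample_ids) != ncol(calls)) {
    stop("sample_ids length (", length(sample_ids),
         ") != calls columns (", ncol(calls), ")")
  }
  if (anyDuplicated(snp_info$snp_id)) stop("duplicate SNP ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype calls must be in {0, 1, 2, NA}")
  dimnames(calls) <- list(snp_info$snp_id, sample_ids)
  structure(
    list(calls = calls, snp_info = snp_info,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "SNPs x", ncol(x$calls), "samples\n")
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Construct an expression matrix
#'
#' Container for a probes x samples real-valued expression matrix. Missing
#' values are rejected: any imputation must happen explicitly before
#' construction.
#'
#' @param values numeric matrix, probes in rows, samples in columns; no
#'   missing values.
#' @param probe_ids character vector of unique probe identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `probe_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || length(probe_ids) != nrow(values)) {
    stop("probe_ids must match the number of rows")
  }
  if (is.null(sample_ids) || length(sample_ids) != ncol(values)) {
    stop("sample_ids must match the number of columns")
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyNA(values)) stop("expression values contain missing entries")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values, probe_ids = as.character(probe_ids),
         sample_ids = as.character(sample_ids)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
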