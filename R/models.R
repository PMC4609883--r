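# Genotype encodings mapping one SNP's minor-allele counts to a two-group
# comparison. For a SNP with major allele A and minor allele T:
#   dominant   — AA (0) vs AT+TT (1,2): presence of any minor allele
#   recessive  — AA+AT (0,1) vs TT (2): two minor alleles required
#   homozygous — AA (0) vs TT (2), heterozygotes (1) excluded
# Missing genotypes are always excluded (per-SNP pairwise exclusion).

GENOTYPE_MODELS <- c("dominant", "recessive", "homozygous")

#' Assign samples to genotype groups under an encoding model
#'
#' @param calls vector of genotype codes in `{0, 1, 2, NA}` (minor-allele
#'   copy counts) for one SNP.
#' @param model `"dominant"` (G1 = 0 vs G2 = 1,2), `"recessive"`
#'   (G1 = 0,1 vs G2 = 2), or `"homozygous"` (G1 = 0 vs G2 = 2,
#'   heterozygotes excluded). Missing calls are always excluded.
#' @return A list of class `group_assignment`: `labels` (character vector in
#'   `{"G1", "G2", "EXCLUDED"}`), counts `m1` and `m2`, and `n_excluded`.
#' @export
assign_groups <- function(calls, model = c("dominant", "recessive", "homozygous")) {
  model <- match.arg(model)
  if (length(calls) == 0) stop("empty call vector")
  labels <- rep("EXCLUDED", length(calls))
  idx1 <- switch(model,
    dominant = which(calls == 0L),
    recessive = which(calls %in% c(0L, 1L)),
    homozygous = which(calls == 0L)
  )
  idx2 <- switch(model,
    dominant = which(calls %in% c(1L, 2L)),
    recessive = which(calls == 2L),
    homozygous = which(calls == 2L)
  )
  labels[idx1] <- "G1"
  labels[idx2] <- "G2"
  structure(
    list(labels = labels, m1 = length(idx1), m2 = length(idx2),
         n_excluded = sum(labels == "EXCLUDED")),
    class = "group_assignment"
  )
}
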