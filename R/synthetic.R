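# Synthetic fixture generator: genotype + expression datasets with a
# planted genotype-dependent correlation structure, so every module is
# testable without any external download. One causal SNP stratifies the
# cohort under a chosen encoding; the planted probe pair is drawn bivariate
# normal with correlation rho1 in group G1 and rho2 in G2. Null SNPs are
# Hardy-Weinberg draws at random common MAFs and null probes are i.i.d.
# standard normal, so the only non-null signal is the planted trio.

#' Specification of a planted differential-correlation dataset
#'
#' @param n_samples cohort size.
#' @param maf minor-allele frequency of the causal SNP, in (0, 0.5].
#' @param model genotype encoding under which the effect is planted.
#' @param rho1,rho2 within-group correlations of the planted probe pair for
#'   G1 and G2, each in (-1, 1).
#' @param rho_het correlation used for heterozygotes when `model =
#'   "homozygous"` excludes them from both groups (default `rho1`;
#'   declared so the heterozygote behavior is explicit and configurable).
#' @param n_null_snps,n_null_probes number of null SNPs (random MAF in
#'   `[0.2, 0.5]`, Hardy-Weinberg) and null probes (i.i.d. standard normal)
#'   added around the planted trio.
#' @param min_group_size smallest acceptable genotype group for the causal
#'   SNP.
#' @param on_degenerate `"regenerate"` (redraw the causal SNP, up to 100
#'   times) or `"fail"` when a drawn causal genotype vector leaves a group
#'   below `min_group_size`.
#' @param seed integer seed; generation is byte-identical for a fixed seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_samples = 200L, maf = 0.3, model = "dominant",
                       rho1 = 0.7, rho2 = 0.0, rho_het = rho1,
                       n_null_snps = 10L, n_null_probes = 20L,
                       min_group_size = 4L,
                       on_degenerate = c("regenerate", "fail"),
                       seed = 1L) {
  model <- match.arg(model, GENOTYPE_MODELS)
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(n_samples >= 8, maf > 0, maf <= 0.5,
            abs(rho1) < 1, abs(rho2) < 1, abs(rho_het) < 1,
            n_null_snps >= 0, n_null_probes >= 0)
  structure(
    list(n_samples = as.integer(n_samples), maf = maf, model = model,
         rho1 = rho1, rho2 = rho2, rho_het = rho_het,
         n_null_snps = as.integer(n_null_snps),
         n_null_probes = as.integer(n_null_probes),
         min_group_size = as.integer(min_group_size),
         on_degenerate = on_degenerate, seed = as.integer(seed)),
    class = "plant_spec"
  )
}

# Hardy-Weinberg genotype draw at a given MAF, recoded so the empirical
# minor-allele frequency is <= 0.5 (ties keep the original coding), which
# keeps the minor designation consistent through a write/read round trip.
draw_hwe_calls <- function(n, maf) {
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  calls <- sample(0:2, n, replace = TRUE, prob = p)
  flipped <- FALSE
  if (mean(calls) / 2 > 0.5) {
    calls <- 2L - calls
    flipped <- TRUE
  }
  list(calls = as.integer(calls), flipped = flipped)
}

#' Generate a dataset with a planted differential-correlation trio
#'
#' Draws the causal SNP from Hardy-Weinberg proportions at `spec$maf`,
#' assigns groups under `spec$model`, and generates the planted probe pair
#' bivariate normal (standard normal margins, via the 2x2 Cholesky factor)
#' with correlation `rho1` for G1 samples, `rho2` for G2, and `rho_het` for
#' samples the encoding excludes. All margins are standard normal, so
#' quantile normalization is approximately an identity on large fixtures
#' and the statistic is isolated from normalization effects.
#'
#' @param spec a [plant_spec()].
#' @return A list with elements `genotypes` ([genotype_matrix]),
#'   `expression` ([expression_matrix]), and `truth` (causal SNP id, planted
#'   probe ids, and the generating parameters).
#' @export
generate_dataset <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  n <- spec$n_samples
  with_preserved_rng({
    set.seed(spec$seed)
    causal <- NULL
    for (try in seq_len(100L)) {
      cand <- draw_hwe_calls(n, spec$maf)
      grp <- assign_groups(cand$calls, spec$model)
      if (grp$m1 >= spec$min_group_size && grp$m2 >= spec$min_group_size) {
        causal <- cand
        break
      }
      if (spec$on_degenerate == "fail") {
        stop("causal SNP draw left a genotype group below min_group_size")
      }
    }
    if (is.null(causal)) {
      stop("could not draw a causal SNP with both groups of size >= ",
           spec$min_group_size, " in 100 attempts")
    }
    grp <- assign_groups(causal$calls, spec$model)

    # planted pair: y = rho * x + sqrt(1 - rho^2) * eps, per-sample rho
    rho <- rep(spec$rho_het, n)
    rho[grp$labels == "G1"] <- spec$rho1
    rho[grp$labels == "G2"] <- spec$rho2
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)

    n_probes <- 2L + spec$n_null_probes
    values <- matrix(NA_real_, nrow = n_probes, ncol = n)
    values[1, ] <- x
    values[2, ] <- y
    if (spec$n_null_probes > 0) {
      values[-(1:2), ] <- stats::rnorm(spec$n_null_probes * n)
    }

    s <- 1L + spec$n_null_snps
    calls <- matrix(NA_integer_, nrow = s, ncol = n)
    calls[1, ] <- causal$calls
    if (spec$n_null_snps > 0) {
      for (k in seq_len(spec$n_null_snps)) {
        calls[k + 1L, ] <- draw_hwe_calls(n, stats::runif(1, 0.2, 0.5))$calls
      }
    }

    snp_ids <- sprintf("rs%05d", seq_len(s))
    probe_ids <- sprintf("probe%04d", seq_len(n_probes))
    sample_ids <- sprintf("sample%04d", seq_len(n))
    g <- genotype_matrix(
      calls,
      data.frame(snp_id = snp_ids, chrom = "1",
                 pos = seq_len(s) * 1000L,
                 major = "A", minor = "T", stringsAsFactors = FALSE),
      sample_ids
    )
    e <- expression_matrix(values, probe_ids, sample_ids)
    truth <- list(snp = snp_ids[1], probe_i = probe_ids[1],
                  probe_j = probe_ids[2], model = spec$model,
                  rho1 = spec$rho1, rho2 = spec$rho2,
                  rho_het = spec$rho_het, maf = spec$maf,
                  n_samples = n, seed = spec$seed,
                  m1 = grp$m1, m2 = grp$m2)
    list(genotypes = g, expression = e, truth = truth)
  })
}

#' Write a generated dataset as an on-disk fixture
#'
#' Serializes to the transposed PLINK text dialect (`fixture.tped` /
#' `fixture.tfam`), a tab-delimited expression matrix (`expression.tsv`),
#' and, when a truth record is supplied, a small `key = value` text file
#' (`truth.txt`), enabling end-to-end command-line tests.
#'
#' @param g a [genotype_matrix].
#' @param e an [expression_matrix].
#' @param dir output directory (created if absent).
#' @param truth optional truth record from [generate_dataset()].
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(g, e, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tped = file.path(dir, "fixture.tped"),
    tfam = file.path(dir, "fixture.tfam"),
    expression = file.path(dir, "expression.tsv")
  )
  write_genotypes_tped(g, paths[["tped"]], paths[["tfam"]])
  write_expression(e, paths[["expression"]])
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.txt")
    writeLines(sprintf("%s = %s", names(truth),
                       vapply(truth, as.character, "")),
               paths[["truth"]])
  }
  paths
}
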