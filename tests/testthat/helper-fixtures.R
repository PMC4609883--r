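# Shared fixtures and independent oracles. The oracles deliberately use a
# different computational path from the package (explicit sum formulas,
# log-ratio z-transform, erfc tail) so agreement is evidence, not tautology.

# --- text fixture builders -------------------------------------------------

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Tiny cohort used across IO tests: 3 SNPs x 4 samples, with a missing call
# and a monomorphic SNP.
tiny_ped_fixture <- function() {
  ped <- c(
    "f1 s1 0 0 1 -9  A A  G G  C C",
    "f2 s2 0 0 1 -9  A T  G G  C C",
    "f3 s3 0 0 2 -9  T T  G T  C C",
    "f4 s4 0 0 2 -9  A T  0 0  C C"
  )
  map <- c(
    "1 snpA 0 1000",
    "1 snpB 0 2000",
    "2 snpC 0 500"
  )
  list(ped = write_lines_tmp(ped, ".ped"), map = write_lines_tmp(map, ".map"))
}

tiny_tped_fixture <- function() {
  tfam <- c(
    "f1 s1 0 0 1 -9", "f2 s2 0 0 1 -9", "f3 s3 0 0 2 -9", "f4 s4 0 0 2 -9"
  )
  tped <- c(
    "1 snpA 0 1000  A A  A T  T T  A T",
    "1 snpB 0 2000  G G  G G  G T  0 0",
    "2 snpC 0 500   C C  C C  C C  C C"
  )
  list(tped = write_lines_tmp(tped, ".tped"),
       tfam = write_lines_tmp(tfam, ".tfam"))
}

# Random genotype matrix whose minor-allele coding is consistent (empirical
# minor frequency <= 0.5 per SNP), as required at load time.
random_genotypes <- function(n_snps, n_samples, seed,
                             missing_rate = 0.05) {
  set.seed(seed)
  calls <- matrix(NA_integer_, n_snps, n_samples)
  for (k in seq_len(n_snps)) {
    maf <- runif(1, 0.2, 0.5)
    p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    x <- sample(0:2, n_samples, replace = TRUE, prob = p)
    if (mean(x) / 2 > 0.5) x <- 2L - x
    x[runif(n_samples) < missing_rate] <- NA_integer_
    if (all(is.na(x))) x[1] <- 0L
    calls[k, ] <- as.integer(x)
  }
  genotype_matrix(
    calls,
    data.frame(snp_id = sprintf("rs%04d", seq_len(n_snps)), chrom = "1",
               pos = seq_len(n_snps), major = "A", minor = "T",
               stringsAsFactors = FALSE),
    sprintf("s%03d", seq_len(n_samples))
  )
}

random_expression <- function(n_probes, n_samples, seed) {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_probes * n_samples), n_probes, n_samples),
    sprintf("p%03d", seq_len(n_probes)),
    sprintf("s%03d", seq_len(n_samples))
  )
}

# --- independent oracles ---------------------------------------------------

# Pearson correlation from explicit sums (no stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Differential-correlation statistic from first principles: log-ratio
# z-transform and the complementary-error-function normal tail.
oracle_z_stat <- function(r1, m1, r2, m2) {
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  z <- abs(z1 - z2) / sqrt(1 / (m1 - 3) + 1 / (m2 - 3))
  list(Z = z, p = pracma::erfc(z / sqrt(2)))
}

# Naive reference scan: triple loop over SNP x probe-pair, one correlation
# call per pair. Same statistic definition, opposite organization to the
# blocked engine.
naive_scan <- function(g, e, model = "dominant", min_group_size = 4L) {
  probe_ord <- order(e$probe_ids, method = "radix")
  probe_ids <- e$probe_ids[probe_ord]
  values <- e$values[probe_ord, , drop = FALSE]
  t_probes <- length(probe_ids)
  rows <- list()
  for (k in seq_len(nrow(g$calls))) {
    grp <- assign_groups(g$calls[k, ], model)
    if (grp$m1 < min_group_size || grp$m2 < min_group_size) next
    i1 <- grp$labels == "G1"
    i2 <- grp$labels == "G2"
    for (i in seq_len(t_probes - 1)) {
      for (j in seq((i + 1), t_probes)) {
        x1 <- values[i, i1]; y1 <- values[j, i1]
        x2 <- values[i, i2]; y2 <- values[j, i2]
        if (sd(x1) == 0 || sd(y1) == 0 || sd(x2) == 0 || sd(y2) == 0) next
        st <- z_statistic(cor(x1, y1), grp$m1, cor(x2, y2), grp$m2,
                          min_group_size)
        rows[[length(rows) + 1L]] <- data.frame(
          snp = g$snp_info$snp_id[k], probe_i = probe_ids[i],
          probe_j = probe_ids[j], r1 = st$r1, r2 = st$r2,
          m1 = grp$m1, m2 = grp$m2, Z = st$Z, p = st$p,
          clamped = st$clamped, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$snp, out$probe_i, out$probe_j, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Bivariate-normal group pair with target correlation (oracle-side
# generator for calibration checks).
rbvn_pair <- function(m, rho) {
  x <- rnorm(m)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(m)
  cbind(x, y)
}

# Row-wise Pearson correlation between paired halves of a matrix: xs, ys are
# reps x m matrices; returns one r per row. Used to vectorize calibration
# simulations.
rowwise_cor <- function(xs, ys) {
  xc <- xs - rowMeans(xs)
  yc <- ys - rowMeans(ys)
  rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
}
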