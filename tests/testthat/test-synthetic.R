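test_that("generation is byte-identical for a fixed seed", {
  spec <- plant_spec(seed = 123)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  d <- generate_dataset(plant_spec(seed = 124))
  expect_false(identical(a$expression$values, d$expression$values))
})

test_that("planted within-group correlations recover their targets", {
  # at n = 200 and MAF 0.3 each group holds ~100 samples, so a single
  # within-group correlation estimate has sampling sd near 0.1; check the
  # mean over seeds tightly and each individual estimate loosely (3.5 sd)
  est <- vapply(131:145, function(seed) {
    ds <- generate_dataset(plant_spec(seed = seed, rho1 = 0.7, rho2 = 0,
                                      n_samples = 200, maf = 0.3))
    grp <- assign_groups(ds$genotypes$calls[1, ], ds$truth$model)
    x <- ds$expression$values[1, ]
    y <- ds$expression$values[2, ]
    expect_equal(ds$truth$m1 + ds$truth$m2, 200)
    c(r1 = cor(x[grp$labels == "G1"], y[grp$labels == "G1"]),
      r2 = cor(x[grp$labels == "G2"], y[grp$labels == "G2"]))
  }, c(r1 = 0, r2 = 0))
  expect_lt(abs(mean(est["r1", ]) - 0.7), 0.06)
  expect_lt(abs(mean(est["r2", ]) - 0.0), 0.06)
  expect_true(all(abs(est["r1", ] - 0.7) < 0.35))
  expect_true(all(abs(est["r2", ] - 0.0) < 0.35))
})

test_that("causal-SNP minor coding stays consistent with its labels", {
  for (seed in 1:10) {
    ds <- generate_dataset(plant_spec(seed = seed, maf = 0.5,
                                      n_samples = 40))
    f <- apply(ds$genotypes$calls, 1, minor_allele_frequency)
    expect_true(all(f <= 0.5))
  }
})

test_that("equal planted correlations give a Bonferroni-quiet null dataset", {
  survivors <- vapply(1:10, function(seed) {
    ds <- generate_dataset(plant_spec(seed = seed, rho1 = 0.3, rho2 = 0.3,
                                      n_samples = 120, n_null_snps = 4,
                                      n_null_probes = 8))
    run_scan(ds$genotypes, ds$expression, scan_config())$summary$n_significant
  }, numeric(1))
  # expected survivors per dataset is alpha = 0.05; ten datasets should not
  # produce more than a handful in total
  expect_lte(sum(survivors), 3)
})

test_that("a homozygous-model plant excludes heterozygotes yet is detectable", {
  ds <- generate_dataset(plant_spec(seed = 141, model = "homozygous",
                                    rho1 = 0.75, rho2 = 0, rho_het = 0.75,
                                    n_samples = 300, maf = 0.4,
                                    n_null_snps = 3, n_null_probes = 6))
  grp <- assign_groups(ds$genotypes$calls[1, ], "homozygous")
  expect_true(all(grp$labels[ds$genotypes$calls[1, ] == 1L] == "EXCLUDED"))
  sc <- run_scan(ds$genotypes, ds$expression,
                 scan_config(model = "homozygous", p_threshold = 1))
  best <- sc$results[which.min(sc$results$p), ]
  expect_equal(best$snp, ds$truth$snp)
  expect_equal(best$probe_i, ds$truth$probe_i)
  expect_equal(best$probe_j, ds$truth$probe_j)
  # with rho_het = rho1 the dominant G2 mixes strong-correlation
  # heterozygotes with null minor homozygotes, diluting but not reversing
  # the contrast: the planted trio keeps the constructed direction r1 > r2
  scd <- run_scan(ds$genotypes, ds$expression,
                  scan_config(model = "dominant", p_threshold = 1))
  planted <- scd$results[scd$results$snp == ds$truth$snp &
                           scd$results$probe_i == ds$truth$probe_i &
                           scd$results$probe_j == ds$truth$probe_j, ]
  expect_equal(nrow(planted), 1L)
  expect_gt(planted$r1, planted$r2)
})

test_that("write_fixture round-trips through the tped dialect", {
  ds <- generate_dataset(plant_spec(seed = 151, n_null_snps = 3,
                                    n_null_probes = 4, n_samples = 50))
  dir <- tempfile()
  paths <- write_fixture(ds$genotypes, ds$expression, dir, ds$truth)
  expect_true(all(file.exists(paths)))
  g2 <- read_genotypes_tped(paths[["tped"]], paths[["tfam"]])
  e2 <- read_expression(paths[["expression"]])
  expect_identical(g2$calls, ds$genotypes$calls)
  expect_equal(e2$values, ds$expression$values, tolerance = 1e-12)
  truth_lines <- readLines(paths[["truth"]])
  expect_true(any(grepl("^snp = rs00001$", truth_lines)))
})
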