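test_that("scan bookkeeping: evaluated + skipped equals the designed count", {
  g <- random_genotypes(1, 40, seed = 21, missing_rate = 0)
  e <- random_expression(3, 40, seed = 22)
  sc <- run_scan(g, e, scan_config(p_threshold = 1))
  s <- sc$summary
  expect_equal(s$n_trios, 3)
  expect_equal(s$n_evaluated + s$n_skipped_small_group + s$n_skipped_constant,
               s$n_trios)
  expect_equal(nrow(sc$results), s$n_evaluated)
})

test_that("a monomorphic SNP is skipped wholesale as a small group", {
  set.seed(24)
  calls <- rbind(rep(0L, 30),
                 sample(c(0L, 1L, 2L), 30, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)))
  g <- genotype_matrix(
    calls,
    data.frame(snp_id = c("mono", "poly"), chrom = "1", pos = 1:2,
               major = "A", minor = c(NA, "T")),
    sprintf("s%03d", 1:30)
  )
  e <- random_expression(5, 30, seed = 23)
  sc <- run_scan(g, e, scan_config(p_threshold = 1))
  expect_equal(sc$summary$n_skipped_small_group, 10)
  expect_false("mono" %in% sc$results$snp)
})

test_that("probes constant within a group skip their trios, counted", {
  g <- random_genotypes(2, 30, seed = 31, missing_rate = 0)
  e <- random_expression(6, 30, seed = 32)
  e$values[4, ] <- 3.14  # constant everywhere, hence within every group
  sc <- run_scan(g, e, scan_config(p_threshold = 1))
  expect_equal(sc$summary$n_skipped_constant, 2 * 5)  # 2 SNPs x pairs with p004
  expect_false(any(sc$results$probe_i == "p004" | sc$results$probe_j == "p004"))
  s <- sc$summary
  expect_equal(s$n_evaluated + s$n_skipped_small_group + s$n_skipped_constant,
               s$n_trios)
})

test_that("blocked engine equals the naive triple loop on a random instance", {
  g <- random_genotypes(5, 60, seed = 41)
  e <- random_expression(20, 60, seed = 42)
  sc <- run_scan(g, e, scan_config(p_threshold = 1))
  nv <- naive_scan(g, e)
  expect_equal(sc$results[names(nv)], nv, tolerance = 1e-14)
  # chunked computation is exact regardless of block width
  sc_chunk <- run_scan(g, e, scan_config(p_threshold = 1, chunk_size = 3L))
  expect_identical(sc_chunk$results, sc$results)
})

test_that("scan output is invariant to SNP and probe input order", {
  g <- random_genotypes(4, 50, seed = 51)
  e <- random_expression(8, 50, seed = 52)
  ref <- run_scan(g, e, scan_config(p_threshold = 1))
  set.seed(53)
  gs <- sample(nrow(g$calls))
  ps <- sample(nrow(e$values))
  g2 <- genotype_matrix(g$calls[gs, ], g$snp_info[gs, ], g$sample_ids)
  e2 <- expression_matrix(e$values[ps, ], e$probe_ids[ps], e$sample_ids)
  shuf <- run_scan(g2, e2, scan_config(p_threshold = 1))
  expect_identical(shuf$results, ref$results)
  expect_identical(shuf$summary, ref$summary)
})

test_that("each unordered probe pair appears once, in canonical order", {
  g <- random_genotypes(3, 40, seed = 61)
  e <- random_expression(7, 40, seed = 62)
  sc <- run_scan(g, e, scan_config(p_threshold = 1))
  expect_true(all(sc$results$probe_i < sc$results$probe_j))
  key <- paste(sc$results$snp, sc$results$probe_i, sc$results$probe_j)
  expect_false(anyDuplicated(key) > 0)
})

test_that("degenerate scan inputs are fatal", {
  g <- random_genotypes(2, 20, seed = 71)
  e <- random_expression(1, 20, seed = 72)
  expect_error(run_scan(g, e), "at least 1 SNP and 2 probes")
  e5 <- random_expression(5, 25, seed = 73)
  expect_error(run_scan(g, e5), "not aligned")
})

test_that("BH correction selects by the step-up cutoff over evaluated trios", {
  ds <- generate_dataset(plant_spec(seed = 81, rho1 = 0.8, rho2 = 0,
                                    n_null_snps = 3, n_null_probes = 8))
  all_p <- run_scan(ds$genotypes, ds$expression,
                    scan_config(p_threshold = 1))$results$p
  bh <- run_scan(ds$genotypes, ds$expression,
                 scan_config(correction = "bh", alpha = 0.05))
  expect_equal(bh$summary$n_significant, sum(bh_fdr(all_p, 0.05)))
  expect_true(all(bh$results$p <= bh$summary$threshold))
})

test_that("count_unique reports distinct SNPs, probes, and pairs", {
  res <- data.frame(
    snp = c("s1", "s1", "s2"),
    probe_i = c("a", "a", "a"), probe_j = c("b", "c", "b"),
    stringsAsFactors = FALSE
  )
  expect_equal(count_unique(res),
               c(n_snps = 2L, n_probes = 3L, n_pairs = 2L))
  expect_equal(count_unique(res[0, ]),
               c(n_snps = 0L, n_probes = 0L, n_pairs = 0L))
})

test_that("identical inputs and config give byte-identical output files", {
  ds <- generate_dataset(plant_spec(seed = 91, n_null_snps = 3,
                                    n_null_probes = 6))
  cfg <- scan_config(p_threshold = 0.01)
  f1 <- tempfile(); f2 <- tempfile()
  write_results(run_scan(ds$genotypes, ds$expression, cfg)$results, f1)
  write_results(run_scan(ds$genotypes, ds$expression, cfg)$results, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1L)
})
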