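Package: dcvar
Title: Differential Co-Expression QTL Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scan for common variants whose genotype stratifies
    samples into two groups with significantly different Pearson correlation
    between pairs of expression probes (differential co-expression QTL).
    Implements genotype-stratified correlation testing via the Fisher r-to-z
    two-sample statistic under dominant, recessive, and homozygous encodings;
    PLINK-style text genotype input (.ped/.map, .tped/.tfam); minor-allele
    frequency and variance filters with per-transcript rank-based
    inverse-normal quantile normalization; Bonferroni and Benjamini-Hochberg
    multiple-testing correction; a genotype-permutation estimator of the
    family-wise false positive rate; and a synthetic fixture generator with
    planted genotype-dependent correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
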