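---
title: "Differential co-expression QTL scanning with dcvar: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression QTL scanning with dcvar: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcvar)
```

## The problem

Expression QTL (eQTL) analyses ask whether a variant's genotype shifts the
*mean* expression of a gene. dcvar asks a complementary question: does the
genotype change the *correlation* between two genes' expression? A variant
with this behavior — a differential co-expression QTL — stratifies a cohort
into genotype groups whose co-expression structure differs, which is a
useful intermediate molecular phenotype for variants that standard eQTL
models leave unexplained. The scan is brute-force by design: every SNP is
tested against every unordered pair of expression probes, so a dataset of
$S$ SNPs and $T$ probes defines $S \cdot T(T-1)/2$ trio hypotheses.

## The statistic

For one SNP, samples are split into genotype groups $G_1$ and $G_2$ (sizes
$m_1$, $m_2$) by one of three encodings of the minor-allele count $\{0, 1,
2\}$:

* **dominant** (default): $G_1 = \{0\}$ vs $G_2 = \{1, 2\}$ — presence of
  any minor allele. At the common-variant allele frequencies the scan
  targets (MAF $\ge 0.2$), this encoding best balances the two group sizes.
* **recessive**: $G_1 = \{0, 1\}$ vs $G_2 = \{2\}$.
* **homozygous**: $G_1 = \{0\}$ vs $G_2 = \{2\}$, heterozygotes excluded.

Missing genotypes are always excluded, per SNP (pairwise exclusion), so a
sample missing at one SNP still contributes to every other SNP's tests.

For a probe pair $(i, j)$, the within-group Pearson correlations
$r^{(1)}_{ij}$ and $r^{(2)}_{ij}$ are Fisher z-transformed,
$z = \operatorname{arctanh}(r)$, and compared with

$$
Z_{ij} \;=\; \frac{\left| \operatorname{arctanh}(r^{(1)}_{ij}) -
                   \operatorname{arctanh}(r^{(2)}_{ij}) \right|}
       {\sqrt{\dfrac{1}{m_1 - 3} + \dfrac{1}{m_2 - 3}}},
\qquad
p = 2\,\bigl(1 - \Phi(Z_{ij})\bigr).
$$

This is the textbook two-sample z-test for comparing independent
correlations: $\operatorname{arctanh}(r)$ is approximately normal with
variance $1/(m-3)$, the denominator is the standard deviation of the
difference, and the absolute value makes the test two-sided. Two details
are deliberate and worth stating because variant renderings of this test
exist in the literature:

* the z-transform is **signed** — applying it to $|r|$ would make
  $r = -0.9$ and $r = +0.9$ indistinguishable, collapsing exactly the
  contrasts a differential-correlation scan exists to find;
* the denominator carries the **square root** — without it the statistic
  is mis-scaled and its null distribution is not standard normal. The
  package's null-calibration tests (rejection rate at $\alpha = 0.05$
  inside the exact binomial interval over 10,000 replicates) only hold for
  this form.

## Numerical choices and degenerate inputs

* **Minimum group size.** The variance term requires $m > 3$; the default
  `min_group_size = 4` is that mathematical floor. Trios with a smaller
  group are *skipped and counted*, never assigned $p = 1$, so the
  multiple-testing denominator stays honest. For noisy data a larger value
  (e.g. 10) is a reasonable stabilizer — see the tail-calibration
  limitation below.
* **Perfect correlations.** $|r| = 1$ (possible at small $m$) would send
  $\operatorname{arctanh}$ to infinity; $r$ is clamped to
  $\pm(1 - 10^{-15})$ and the trio flagged `clamped`, preserving extreme
  significance without infinities.
* **Constant expression within a group** makes the correlation undefined;
  such trios are skipped and counted under their own reason.
* **Tie-breaks.** Probe pairs are canonicalized `probe_i < probe_j` in
  C-locale lexicographic order and results sorted by (snp, probe_i,
  probe_j), so output is byte-identical across runs and invariant to input
  row order. A minor-allele frequency of exactly 0.5 designates the
  lexicographically smaller allele character as major.
* **p-value floor.** `2 * pnorm(Z, lower.tail = FALSE)` underflows to 0
  near $Z \approx 38.6$; p-values are floored at the smallest positive
  double so the invariant $p > 0$ holds and text output stays finite.

## Multiple testing

The designed family is all $S \cdot T(T-1)/2$ trios, *including* skipped
ones — skipping a trio for data reasons does not earn the survivors a
laxer threshold. The default correction is Bonferroni,
$p \le \alpha / (S \cdot T(T-1)/2)$; at the genome scale the package was
designed around ($S = 70{,}716$, $T = 10{,}000$, $\alpha = 0.05$) this
gives the $1.41 \times 10^{-14}$ threshold that
`bonferroni_threshold(0.05, 70716, 10000)` reproduces, and
$1.0 \times 10^{-9}$ for a single variant. A Benjamini–Hochberg step-up
option (`correction = "bh"`) offers FDR control for users who find
family-wise control too stringent; it is applied over all evaluated trios,
which requires materializing their p-values and is therefore intended for
desk-scale analyses. Under Bonferroni the scan streams and prunes per SNP
and never holds the full trio set.

## Permutation estimate of the family-wise false-positive rate

`permute_genotypes()` permutes each SNP's call vector across samples
independently, expression held fixed. This preserves every per-SNP genotype
count (hence MAF and group sizes) exactly while destroying any
genotype–expression association; it also destroys LD between SNPs, which is
the published protocol's behavior (a sample-level permutation preserving LD
is available via `per_snp = FALSE`). Per-SNP permutation streams are seeded
from a hash of the SNP id combined with the master seed, so results do not
depend on SNP iteration order. `permutation_null()` repeats the scan over
replicates; at a Bonferroni threshold of $\alpha / n_\text{tests}$ the
expected survivor count per whole-scan replicate is approximately $\alpha$.

**Limitation — deep-tail calibration.** The normal approximation behind the
test is excellent near conventional significance levels but anticonservative
deep in the tail when a group is small: by direct simulation, at a
$4 \times 10^{-6}$ threshold the realized rejection rate is about 1.15× the
nominal rate for $m_1 = m_2 = 50$ but about 2.4× for $m_1 = 25, m_2 = 75$.
Genome-scale thresholds live far out in this tail, which is one reason the
MAF $\ge 0.2$ filter and the dominant encoding (both of which keep groups
large and balanced) matter, and why raising `min_group_size` is advisable on
small cohorts. The package's permutation acceptance check therefore uses
cohorts of $n = 200$, where groups stay near or above 50.

## Preprocessing

* `filter_snps_by_maf()` keeps SNPs with allele frequencies inside an
  inclusive window, default $[0.2, 0.8]$ — i.e. MAF $\ge 0.2$ under
  minor-allele coding. Common variants keep both genotype groups large.
* `quantile_normalize()` applies a rank-based inverse-normal transform per
  transcript: the value at ascending rank $k$ of $n$ maps to
  $\Phi^{-1}((k - 0.5)/n)$. The $-0.5$ offset is the conventional
  symmetric choice and is stated exactly so tests can be exact; ties get
  average ranks, making the transform deterministic on tied intensities
  (a fully constant transcript maps to all zeros and is subsequently
  skipped as degenerate). Because only ranks matter, the transform is
  idempotent and invariant to monotone rescaling. It also removes
  per-transcript scale and distributional differences, which in
  multi-population cohorts absorbs much of the broad ancestry signal.
* `variance_filter()` keeps the `top_n` probes by unbiased sample variance
  ($n - 1$ divisor), applied after quantile normalization in the standard
  pipeline; exact ties at the cutoff break by probe id so the selection is
  reproducible.

LD pruning, Hardy–Weinberg filtering, and SNP/sample missingness QC are out
of scope: the package assumes genotypes already cleaned by standard tools
(e.g. PLINK) and applies only the MAF window and per-SNP missing-call
exclusion itself.

## The synthetic generator: what it emulates and what it does not

`generate_dataset(plant_spec(...))` builds a cohort with one causal SNP
drawn from Hardy–Weinberg proportions at a chosen MAF, a planted probe pair
whose within-group correlations are `rho1` (G1) and `rho2` (G2) under the
chosen encoding, plus null SNPs (random MAF in $[0.2, 0.5]$, Hardy–Weinberg)
and i.i.d. standard-normal null probes. The bivariate pairs are generated
through the 2×2 Cholesky factor with standard-normal margins, so quantile
normalization is approximately an identity on these fixtures and the
statistic is exercised in isolation from normalization effects. When the
homozygous encoding excludes heterozygotes, their expression still needs a
generating law; the default assigns them `rho1` (configurable via
`rho_het`) — an arbitrary but declared choice.

Defaults — $n = 200$ samples, causal MAF 0.3, `rho1 = 0.7`, `rho2 = 0`,
dominant model, 10 null SNPs, 20 null probes — are the desk-scale study
conditions used throughout the test suite: large enough that group sizes
sit near 100 where the z-approximation is accurate, small enough that a
full scan of the $11 \times 231 = 2{,}541$ trios takes milliseconds.

What the generator does **not** emulate: LD between SNPs, population
stratification, microarray noise models, mean-expression QTL effects, and
RNA-Seq count distributions. Passing tests on these fixtures therefore
demonstrate the correctness and calibration of the statistic, the scan
bookkeeping, and the permutation protocol — not robustness to the
correlated, stratified, heavy-tailed structure of real cohorts. Pearson
correlation in particular is outlier-sensitive; rank-based or bootstrap
variants are deliberately out of scope.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data:
1,000 random trios for oracle agreement (relative error below $10^{-12}$
against an independently coded brute-force statistic); 10,000 null
replicates at $m_1 = m_2 = 50$, $\rho = 0.3$ for calibration at
$\alpha = 0.05$; 200 permutation replicates of a 10-SNP × 50-probe null
scan at its instance-level Bonferroni threshold ($0.05/12{,}250$); and
100 seeds of the default planted fixture for recovery (the planted trio
should attain the scan's minimum p-value in at least 95% of seeds, with
power monotone in the z-scale gap
$|\operatorname{arctanh}\rho_1 - \operatorname{arctanh}\rho_2|$ across
$\{0.2, 0.4, 0.6\}$). These sizes make the whole suite run in well under a
minute while leaving each check statistically sharp.

## Interface notes

The scan, permutation, and simulation engines are exported R functions; the
installed `scripts/dcvar` Rscript wraps them as `scan`, `permute`, and
`simulate` subcommands with every flag mirrored by a plain-text
`key = value` config file (explicit flags win). An explicit `--p-threshold`
overrides the `--alpha`/`--correction` arithmetic; either way the effective
threshold is logged. Results are TSV with p-values in scientific notation
at six significant digits, so $10^{-14}$-scale thresholds survive the text
round trip; a small synthetic demo fixture ships under
`inst/extdata/demo/`.
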