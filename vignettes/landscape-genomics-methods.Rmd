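---
title: "Methods: selection scans and environmental association in altiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and environmental association in altiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiscan)
```

altiscan detects signatures of environmental adaptation in structured
populations from genome-wide SNP genotypes. It chains the standard
quality-control steps, two complementary selection statistics — the
population branch statistic (PBS) for a designated focal group, and
Bayes-factor genotype–environment association across a panel of climatic
covariates — and downstream gene cataloguing and candidate-set enrichment.
This vignette documents the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic-data tests do and do not
demonstrate.

## Quality control

Marker filters are applied in a fixed order: site quality (phred QUAL ≥ 40),
overall call rate (≥ 0.8), biallelic SNPs only, exact Hardy–Weinberg test
(p ≥ 1e-8, computed over all samples pooled, since the corresponding VCF
site filter operates on the whole file), minor allele frequency (≥ 0.05,
boundary inclusive), per-population call rate (≥ 0.8 in *every*
population), and removal of sites monomorphic across all study populations.
All thresholds are inclusive because the conventional command-line flags
they mirror state no boundary semantics; the report records per-stage
removals, which are additive by construction, and re-filtering the output
is a no-op.

The Hardy–Weinberg p-value is a two-sided exact test: conditional on the
observed allele counts, every heterozygote count of matching parity is
enumerated, its conditional probability computed in log space, and
probabilities no larger than that of the observed configuration summed.
No chi-square approximation is used anywhere; the tail behaviour of the
exact test matters at the extreme 1e-8 threshold.

Relatedness is measured with the KING-robust kinship estimator
$\phi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa}(i) + N_{Aa}(j))$, which is
insensitive to population structure. Samples are removed greedily: while
any pair exceeds the second-degree cutoff (0.0884), the sample with the
most above-threshold partners is dropped, ties broken by smallest sample
id. The greedy max-degree rule keeps more samples than removing one sample
per offending pair and guarantees the "no close relatives" post-condition;
the choice is a design decision, as relative-removal orders are not
uniquely determined by the cutoff alone.

LD pruning is a greedy left-to-right scan: each retained marker is
correlated (Pearson on dosages, missing values pairwise-deleted) against
every later marker within a 500 kb physical window; the later marker is
pruned when r² exceeds the threshold (0.8 for the main set, 0.5 for the
stringent comparison set used in covariate ranking). Dosage correlation
rather than haplotype r² is used because genotypes are unphased.
Zero-variance markers have undefined r² and are deliberately never pruned
by LD — they are the monomorphism filter's job. The scan is implemented in
C++ because it is the one QC step that is quadratic within windows.

Per-site nucleotide diversity is $\pi = x(n-x)/\binom{n}{2}$ — the
fraction of discordant chromosome pairs — rather than expected
heterozygosity; a single called diploid (two chromosomes) is the minimum
informative site.

## Population differentiation: Weir–Cockerham F\_ST and PBS

Pairwise differentiation uses the Weir & Cockerham (1984) two-population
moment estimator $\theta = a/(a+b+c)$ from the among-population (a),
among-individual (b) and within-individual (c) variance components,
computed per SNP from sample sizes, allele frequencies and *observed*
heterozygote proportions. Per-SNP estimates may be negative and are clamped
to zero before any transformation; genome-wide averages are ratios of
summed components, not means of ratios. Sites are evaluated with
pairwise-complete samples (a genotype missing in one sample does not
discard the site).

The population branch statistic for focal group A against sister B and
outgroup C is

$$\mathrm{PBS}_A = \tfrac{1}{2}\left(T_{AB} + T_{AC} - T_{BC}\right),
\qquad T = -\ln(1 - F_{ST}),$$

with the natural logarithm (the original formulation). Populations are
pooled into the three groups *before* allele counting, which raises the
effective sample size of each branch. An F\_ST of exactly 1 would give an
infinite branch length; T is capped at $-\ln(10^{-6})$, which preserves
rankings without propagating infinities into window statistics.

Window statistics are means and medians of 9 consecutive defined SNPs
centered on each marker, never spanning chromosome boundaries; markers
without a complete window of defined values (chromosome edges, sites with
undefined F\_ST) carry missing window values. This complete-window rule is
why the windowed marker count is smaller than the raw count.

## Genotype–environment association

The association model treats the vector of standardized sample allele
frequencies at a SNP, $\hat u_j = (\hat p_j - \hat p)/\sqrt{\hat p(1-\hat
p)}$ over populations $j$, as

$$\hat u \sim \mathcal{N}\!\left(\beta Z,\; \Omega + D\right),$$

where $Z$ is the covariate standardized to zero mean and unit variance
across sampled locations, $\Omega$ is the covariance of standardized
population frequencies (shared demographic history), and $D$ is the
diagonal binomial sampling variance of each $\hat p_j$ given its
chromosome count, rescaled by $\hat p(1-\hat p)$. The Bayes factor
integrates $\beta$ over a uniform prior on $(-0.3, 0.3)$ — the documented
default of the reference implementation of this model class — by
fixed-grid quadrature with 201 nodes, against the point null $\beta = 0$,
and is reported in deciban: $10\log_{10}\mathrm{BF}$, with BF > 10 dB the
conventional "strong evidence" threshold. Refining the grid to 2001 nodes
moves results by under 0.1 dB, so 201 is treated as converged.

**This is a deliberate Gaussian approximation** of the hierarchical
binomial model that sampler-based tools fit by MCMC. It keeps the two
structural ingredients that matter — the $\Omega$-correlated null and the
uniform effect prior — while making the statistic deterministic, fast and
unit-testable against a direct multivariate-normal quadrature oracle. It
is not a numerical clone of any external sampler.

$\Omega$ is estimated by the method of moments: the sample covariance of
$\hat u$ across a SNP subsample, shrunk toward its diagonal by
$\lambda = 0.05$. Because deviations are centered on the pooled frequency,
the raw covariance is always singular in one direction, so the shrinkage
is structurally necessary, not cosmetic; the estimate also absorbs the
centering projection and average sampling noise, which the tests account
for explicitly when comparing against a known simulated truth.

The replicate protocol runs the scan `n_runs` times (100 by default,
matching the convention of averaging over repeated MCMC runs), with each
replicate re-estimating $\Omega$ from a fresh seeded 50,000-SNP subsample —
the deterministic analogue of between-run sampler variability. Per-SNP
Bayes factors are averaged arithmetically on the dB scale. Covariates are
ranked by the run-averaged count of markers exceeding 10 dB on the
stringently LD-pruned (r² ≤ 0.5) set.

## Outlier genes and enrichment

Top-quantile SNP sets take the $\lceil fM \rceil$ largest defined values
at tiers $10^{-5}$, $10^{-4}$, $10^{-3}$, with ties at the cutoff all
included (proportions define no tie rule, so inclusion is the
conservative choice). Gene cataloguing intersects outlier SNPs with gene
intervals directly and within 100 kb, where "within 100 kb" is strictly
less than 100,000 bp from the nearest gene edge. Coordinates are 0-based
half-open internally; VCF positions are converted from 1-based on read and
GFF3 from 1-based inclusive. Strand is ignored — distance is
strand-agnostic. Gene sets are pooled (union) across the raw, window-mean
and window-median variants of each test.

Candidate-gene enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ for $k$ overlaps between a size-$n$ query set and a size-$K$
candidate list in a universe of $N$ genes (default 13,510 autosomal
protein-coding genes), with fold enrichment $k/(nK/N)$. The tail is exact
rather than approximated because the interesting p-values sit far out in
the tail where normal approximations fail. Symbols containing "ORF" are
excluded from both lists (function unknown), and matching is
case-insensitive after trimming. The universe is a configurable count, not
a symbol list, because filtering to autosomal protein-coding genes happens
upstream of this module; both pre- and post-exclusion list sizes are
reported since published totals do not state which convention they use.

## PCA summaries

Environment PCA centers and scales the 20 covariates and decomposes by
SVD; variance fractions are squared singular values over their sum.
Genotype PCA mean-imputes missing dosages per SNP, standardizes columns by
$\sqrt{2p(1-p)}$ (the usual population-structure scaling; the behavior is
documented here explicitly because tool defaults differ), and decomposes
the sample × SNP matrix. Components are oriented so each loading vector's
largest-magnitude element is positive, since SVD signs are arbitrary.

## The synthetic-data generator

The generator is the package's ground-truth surface. Ancestral frequencies
are uniform on (0.05, 0.95); per-SNP standardized population deviations
are multivariate normal with covariance `omega_true`; population
frequencies are $\pi + \alpha^*\sqrt{\pi(1-\pi)}$, clamped to
[0.001, 0.999] to avoid degenerate binomial draws (a warning fires if more
than 10% of draws hit the clamp). Environment-associated loci add
$\beta Z_j$ to the standardized deviation; branch loci add a fixed
frequency displacement in the designated populations only. Genotypes are
binomial draws of two alleles.

Defaults were fixed once, on domain grounds: `omega_true` diagonal 0.02,
matching the low differentiation typical of regional livestock populations
(pairwise F\_ST a few percent); covariates in two correlated blocks — a
temperature/altitude block with altitude loading negatively (high sites
are cold) and a precipitation block — plus weakly structured seasonality
variables, emulating the usual two-axis structure of bioclimatic tables;
SNP positions uniform per chromosome with **no linkage disequilibrium**
(an optional copy-with-noise mode plants near-r²=1 duplicates purely to
exercise the pruner).

What passing synthetic tests show — and what they do not. The generator
draws each SNP independently, so a planted selected locus is a *single*
SNP: the best case for per-SNP statistics and the worst case for 9-SNP
window statistics, whose value at an isolated outlier is diluted by eight
null neighbours (the window mean rises by only one ninth of the planted
signal). Real selective sweeps elevate extended haplotypes, which is
precisely what window statistics are designed to reward. Consequently, on
synthetic data the raw-PBS top-1% recovery of planted branch loci is high
(≈ 0.85–0.90 at 12 populations × 8 samples, shift 0.4), while window-mean
recovery is structurally limited (≈ 0.3–0.5): the limit is the simulated
data's lack of local signal correlation plus small-sample estimator noise,
not a defect of the statistic — with 30 samples per population the same
window-mean recovery reaches ≈ 0.75–1.0. Similarly, with β = 0.25 and 16
chromosomes per population, per-population sampling variance (1/16)
dominates `omega_true` (0.02), so only a minority of planted
environment loci clear 10 dB, and the planted covariate's count advantage
(a few tens of markers) is comparable to the between-covariate spread of
null counts on a 100,000-marker panel; the planted covariate therefore
ranks near, but not reliably at, the top. The test suite asserts the
strict recovery targets as stated and reports the measured values; this
paragraph is the package's account of why the window-mean and
ranking margins behave as they do under these study conditions.

## Problem sizes and numerical choices

The default test suite exercises panels of 200–8,000 SNPs, where every
statistic is cross-checked against an independent oracle (full enumeration
for the HWE test at up to 20 diploids; a second, independent transcription
of the variance-components estimator at 1e-12; explicit index-slice
windows; all-pairs interval intersection; log-space hypergeometric tail
sums; direct multivariate-normal quadrature for the Bayes factor). The
study-scale recovery experiment runs 100,000 SNPs across 12 populations
with 10 replicate association runs and three seeds. Degenerate inputs have
defined behaviour throughout: monomorphic sites yield missing statistics
(never silent zeros or infinities), undefined kinship pairs are flagged,
zero-variance covariates raise errors, and every stochastic step is
seeded, with the pipeline's global seed expanding deterministically into
per-run seeds.

## Known limitations

* The Bayes factor is a Gaussian approximation; its absolute calibration
  differs from MCMC-based posterior inclusion evidence, although rankings
  agree under the model's assumptions.
* No coalescent simulation: the generator produces neither LD nor realistic
  site-frequency spectra, so window statistics and haplotype-aware methods
  cannot be benchmarked realistically against it.
* The omega moment estimator absorbs centering and sampling-noise
  structure; it is consistent for ranking purposes but is not an unbiased
  estimator of the generative covariance.
* Sex chromosomes are dropped, not modelled.
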