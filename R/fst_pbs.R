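#' Weir-Cockerham F_ST between two population pools
#'
#' Per-SNP moment estimator theta from the three variance components of
#' Weir & Cockerham (1984): `a` among populations, `b` among individuals
#' within populations, `c` within individuals, computed from sample sizes,
#' allele frequencies and observed heterozygote proportions;
#' `theta = a / (a + b + c)`. Raw theta may be negative; [clamp_fst()] maps
#' negatives to zero. The genome-wide average is the ratio of summed
#' components `sum(a) / sum(a + b + c)`, not the mean of ratios.
#'
#' @param counts a [pop_allele_counts()] object.
#' @param pool_a,pool_b group names (rows of `counts`).
#' @return list with `theta` (per SNP, `NA` where undefined: monomorphic
#'   across both pools or insufficient samples), `a`, `b`, `c` component
#'   vectors, and `gw` (genome-wide ratio-of-sums average).
#' @export
wc_fst <- function(counts, pool_a, pool_b) {
  stopifnot(inherits(counts, "pop_counts"),
            pool_a %in% rownames(counts$ac), pool_b %in% rownames(counts$ac))
  comp <- wc_components(
    n1 = counts$n_homref[pool_a, ] + counts$n_het[pool_a, ] +
      counts$n_homalt[pool_a, ],
    n2 = counts$n_homref[pool_b, ] + counts$n_het[pool_b, ] +
      counts$n_homalt[pool_b, ],
    ac1 = counts$ac[pool_a, ], ac2 = counts$ac[pool_b, ],
    het1 = counts$n_het[pool_a, ], het2 = counts$n_het[pool_b, ])
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(is.finite(denom) & denom != 0, comp$a / denom, NA_real_)
  ok <- is.finite(comp$a) & is.finite(denom) & denom != 0
  gw <- sum(comp$a[ok]) / sum(denom[ok])
  list(theta = unname(theta), a = unname(comp$a), b = unname(comp$b),
       c = unname(comp$c), gw = gw)
}

# Two-population variance components of the 1984 moment estimator.
# n1/n2 diploids called, ac1/ac2 alt-allele counts, het1/het2 heterozygote
# counts. Sites with n_bar <= 1 are undefined (NaN via division).
wc_components <- function(n1, n2, ac1, ac2, het1, het2) {
  r <- 2
  p1 <- ifelse(n1 > 0, ac1 / (2 * n1), NaN)
  p2 <- ifelse(n2 > 0, ac2 / (2 * n2), NaN)
  h1 <- ifelse(n1 > 0, het1 / n1, NaN)
  h2 <- ifelse(n2 > 0, het2 / n2, NaN)
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  pq <- p_bar * (1 - p_bar)
  a <- (n_bar / n_c) *
    (s2 - (pq - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (pq - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  bad <- n1 < 1 | n2 < 1 | n_bar <= 1 | n_c <= 0
  a[bad] <- NaN; b[bad] <- NaN; cc[bad] <- NaN
  list(a = a, b = b, c = cc)
}

#' Clamp F_ST estimates into [0, 1]
#'
#' Negative moment estimates are set to 0 before any transformation to
#' branch lengths; values above 1 (not produced by the estimator, but
#' possible on degenerate input) are capped at 1. `NA` propagates.
#' @param theta numeric vector of raw estimates.
#' @return clamped vector.
#' @export
clamp_fst <- function(theta) pmin(pmax(theta, 0), 1)

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` with `T = -log(1 - F_ST)` (natural
#' log): the allele-frequency branch length specific to focal population A
#' against sister B and outgroup C. Inputs must already be clamped to
#' [0, 1]; `F_ST = 1` would give an infinite branch and is capped at
#' `T = -log(1e-6)` so rankings are preserved without propagating
#' infinities into window means.
#'
#' @param fst_ab,fst_ac,fst_bc clamped pairwise F_ST values (vectors).
#' @return PBS for the focal branch; `NA` where any input is `NA`.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  tt <- function(f) -log(pmax(1 - pmin(f, 1), 1e-6))
  (tt(fst_ab) + tt(fst_ac) - tt(fst_bc)) / 2
}

#' PBS scan over a genotype matrix
#'
#' Pools populations into a focal group, a sister group and an outgroup,
#' computes the three pairwise Weir-Cockerham F_ST series, clamps negatives
#' to zero, forms the per-SNP PBS for the focal branch, and attaches 9-SNP
#' window means and medians. Sites missing any pairwise value carry `NA`
#' PBS and are excluded from windows.
#'
#' @param gm a [geno_matrix()].
#' @param focal,sister,outgroup character vectors of population labels
#'   pooled into the three groups.
#' @param k window size in SNPs (odd).
#' @return data.frame (chrom, pos, fst_ab, fst_ac, fst_bc, pbs_raw,
#'   pbs_mean, pbs_median); F_ST columns are clamped.
#' @export
pbs_scan <- function(gm, focal, sister, outgroup, k = 9) {
  counts <- pop_allele_counts(gm, groups = list(A = focal, B = sister,
                                                C = outgroup))
  f_ab <- clamp_fst(wc_fst(counts, "A", "B")$theta)
  f_ac <- clamp_fst(wc_fst(counts, "A", "C")$theta)
  f_bc <- clamp_fst(wc_fst(counts, "B", "C")$theta)
  p <- pbs(f_ab, f_ac, f_bc)
  v <- counts$variants
  win <- sliding_windows(p, v$chrom, k = k)
  data.frame(chrom = v$chrom, pos = v$pos,
             fst_ab = f_ab, fst_ac = f_ac, fst_bc = f_bc,
             pbs_raw = p, pbs_mean = win$mean, pbs_median = win$median)
}

#' Centered sliding-window mean and median
#'
#' For each SNP whose statistic is defined and which has at least
#' `(k - 1) / 2` defined neighbours on each side within the same
#' chromosome, returns the mean and median of the `k` defined values
#' centered on it. Windows never span chromosome boundaries; SNPs without a
#' complete window (chromosome edges, undefined sites) carry `NA`.
#'
#' @param values per-SNP statistic, `NA` where undefined.
#' @param chrom chromosome of each SNP (values sorted by position within
#'   chromosome).
#' @param k window size in SNPs; must be odd.
#' @return data.frame (`mean`, `median`) aligned with the input.
#' @export
sliding_windows <- function(values, chrom, k = 9) {
  stopifnot(length(values) == length(chrom), k %% 2 == 1, k >= 1)
  wmean <- rep(NA_real_, length(values))
  wmed <- wmean
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    def <- idx[!is.na(values[idx])]
    if (length(def) < k) next
    v <- values[def]
    wmean[def] <- zoo::rollmean(v, k, fill = NA)
    wmed[def] <- zoo::rollmedian(v, k, fill = NA)
  }
  data.frame(mean = wmean, median = wmed)
}

#' All pairwise genome-wide F_ST averages
#'
#' Ratio-of-sums Weir-Cockerham averages for every pair of populations,
#' negatives clamped to zero.
#' @param gm a [geno_matrix()].
#' @return data.frame (pop1, pop2, fst).
#' @export
pairwise_fst_matrix <- function(gm) {
  counts <- pop_allele_counts(gm)
  pops <- rownames(counts$ac)
  pairs <- utils::combn(pops, 2)
  fst <- apply(pairs, 2, function(pr)
    max(0, wc_fst(counts, pr[1], pr[2])$gw))
  data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ], fst = fst)
}
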