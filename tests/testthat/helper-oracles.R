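# Independent oracles, kept deliberately separate from the package's code
# paths: direct transcriptions and brute-force enumerations used to freeze
# or cross-check expected values.

# Exact HWE test by full enumeration of genotype configurations: conditional
# on the allele counts, P(config) is proportional to the number of ways of
# arranging the alleles into genotypes, multinomial(N; n0, n1, n2) * 2^n1.
# Works on exact rationals for small N via big integer-free doubles.
hwe_enum_oracle <- function(n0, n1, n2) {
  N <- n0 + n1 + n2
  na <- 2 * n0 + n1
  nb <- 2 * n2 + n1
  if (na == 0 || nb == 0) return(1.0)
  configs <- list()
  for (h in 0:min(na, nb)) {
    if ((na - h) %% 2 != 0 || (nb - h) %% 2 != 0) next
    a0 <- (na - h) / 2
    a2 <- (nb - h) / 2
    if (a0 + h + a2 != N) next
    w <- exp(lfactorial(N) - lfactorial(a0) - lfactorial(h) -
               lfactorial(a2) + h * log(2))
    configs[[length(configs) + 1]] <- c(h = h, w = w)
  }
  tab <- do.call(rbind, configs)
  p <- tab[, "w"] / sum(tab[, "w"])
  obs <- p[tab[, "h"] == n1]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Independent per-SNP transcription of the 1984 two-population
# variance-components estimator, written as a scalar step-by-step
# calculation from genotype vectors (not from count matrices).
wc_theta_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(NA_real_)
  p1 <- sum(g1) / (2 * n1)
  p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1)
  h2 <- mean(g2 == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  if (nbar <= 1) return(NA_real_)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (ssq - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * ssq - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0 || !is.finite(a + b + cc)) return(NA_real_)
  a / (a + b + cc)
}

# Exhaustive all-pairs r^2 (pairwise-deleted Pearson), for LD post-condition
# checks and as a brute-force pruning oracle.
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  vx <- stats::var(x[ok]); vy <- stats::var(y[ok])
  if (vx == 0 || vy == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

ld_prune_bruteforce <- function(geno, chrom, pos, window_bp, r2max) {
  M <- length(pos)
  keep <- rep(TRUE, M)
  for (i in seq_len(M)) {
    if (!keep[i]) next
    j <- i + 1
    while (j <= M && chrom[j] == chrom[i] && pos[j] - pos[i] <= window_bp) {
      if (keep[j] && r2_pair(geno[, i], geno[, j]) > r2max) keep[j] <- FALSE
      j <- j + 1
    }
  }
  which(keep)
}

# Hypergeometric upper tail as an explicit log-space sum over the support.
hyper_tail_oracle <- function(k, N, K, n) {
  if (k <= 0) return(1)
  xs <- k:min(K, n)
  if (length(xs) == 0) return(0)
  lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  sum(exp(lp))
}

# Direct multivariate-normal quadrature Bayes factor for one SNP and one
# covariate: full density evaluation at every grid node (no cancellation
# tricks), used to cross-check the compiled kernel.
bf_db_oracle <- function(u, d, omega, z, prior = c(-0.3, 0.3), n_grid = 201) {
  Sigma <- omega + diag(d)
  ldens <- function(mu) {
    r <- u - mu
    -0.5 * (length(u) * log(2 * pi) + determinant(Sigma)$modulus[1] +
              drop(t(r) %*% solve(Sigma, r)))
  }
  grid <- seq(prior[1], prior[2], length.out = n_grid)
  l1 <- vapply(grid, function(b) ldens(b * z), 0)
  m <- max(l1)
  log_m1 <- m + log(mean(exp(l1 - m)))
  10 * (log_m1 - ldens(0 * z)) / log(10)
}

# Small literal genotype fixture: populations poured into a geno_matrix.
make_gm <- function(geno, chrom = NULL, pos = NULL, pops = NULL,
                    qual = 60) {
  geno <- as.matrix(geno)
  M <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", M)
  if (is.null(pos)) pos <- seq_len(M) * 1000L
  if (is.null(pops)) pops <- rep("popA", nrow(geno))
  geno_matrix(geno,
              data.frame(chrom = chrom, pos = pos,
                         id = paste0("s", seq_len(M)),
                         ref = "A", alt = "G", qual = qual),
              pops)
}

# Random genotype fixture with missingness, two populations.
random_gm <- function(n_per_pop = 10, M = 50, miss = 0.05, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(2 * n_per_pop * M, 2, runif(M, 0.1, 0.9)[
    rep(seq_len(M), each = 2 * n_per_pop)]), 2 * n_per_pop, M)
  g[matrix(runif(length(g)) < miss, nrow(g))] <- NA
  make_gm(g, pops = rep(c("popA", "popB"), each = n_per_pop))
}
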