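# shared small fixture: 12 populations, diagonal omega, one planted covariate
env_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(
        sim_config(n_pops = 12, samples_per_pop = 8, n_snps = 4000,
                   env_loci = c(BIO12 = 40), beta_env = 0.25,
                   omega_true = 0.02, seed = 33))
    cache
  }
})

test_that("omega estimation rejects undersized input and degenerate panels", {
  sim <- env_fixture()
  counts <- pop_allele_counts(sim$genotypes)
  expect_error(estimate_omega(counts, snp_idx = rep(1L, 50)), "polymorphic")
  small <- pop_allele_counts(subset_geno(sim$genotypes,
                                         samples = sim$genotypes$populations
                                         %in% c("pop1", "pop2")))
  expect_error(estimate_omega(small), "4 populations")
  om <- estimate_omega(counts)
  expect_true(isSymmetric(om$omega))
  expect_true(all(diag(om$omega) > 0))
  expect_true(all(eigen(om$omega, only.values = TRUE)$values > 0))
})

test_that("Bayes factors agree with a direct multivariate-normal oracle", {
  sim <- env_fixture()
  gm <- subset_geno(sim$genotypes, variants = 1:200)
  counts <- pop_allele_counts(gm)
  om <- estimate_omega(pop_allele_counts(sim$genotypes), min_snps = 1000)
  Z <- as.matrix(sim$env[, c("BIO12", "altitude")])
  bf <- bayes_factor_scan(counts, Z, om)
  su <- altiscan:::standardized_freqs(counts)
  Zs <- scale(Z)
  for (j in c(1, 7, 50, 123)) {
    for (cv in 1:2) {
      want <- bf_db_oracle(su$u[, j], su$d[, j], om$omega, Zs[, cv])
      expect_equal(unname(bf[j, cv]), want, tolerance = 1e-8)
    }
  }
})

test_that("BF is invariant to affine covariate rescaling and sign flips", {
  sim <- env_fixture()
  counts <- pop_allele_counts(subset_geno(sim$genotypes, variants = 1:300))
  om <- estimate_omega(pop_allele_counts(sim$genotypes))
  z <- sim$env$BIO12
  b0 <- bayes_factor_scan(counts, z, om)
  b_scaled <- bayes_factor_scan(counts, 3.7 * z + 11, om)
  b_flipped <- bayes_factor_scan(counts, -z, om)
  expect_equal(b0, b_scaled, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(b0, b_flipped, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("constant covariates and monomorphic sites are handled explicitly", {
  sim <- env_fixture()
  counts <- pop_allele_counts(subset_geno(sim$genotypes, variants = 1:100))
  om <- estimate_omega(pop_allele_counts(sim$genotypes))
  expect_error(bayes_factor_scan(counts, rep(1, 12), om), "zero variance")
  # a site fixed in every population gets NA, not +-Inf
  gm2 <- subset_geno(sim$genotypes, variants = 1:50)
  gm2$geno[, 7] <- 2L
  bf <- bayes_factor_scan(pop_allele_counts(gm2), sim$env$BIO12, om)
  expect_true(is.na(bf[7, 1]))
  expect_true(all(is.finite(bf[-7, 1])))
})

test_that("quadrature is converged: 201 vs 2001 nodes differ < 0.1 dB", {
  sim <- env_fixture()
  counts <- pop_allele_counts(subset_geno(sim$genotypes, variants = 1:1000))
  om <- estimate_omega(pop_allele_counts(sim$genotypes))
  b1 <- bayes_factor_scan(counts, sim$env$BIO12, om, n_grid = 201L)
  b2 <- bayes_factor_scan(counts, sim$env$BIO12, om, n_grid = 2001L)
  expect_lt(max(abs(b1 - b2), na.rm = TRUE), 0.1)
})

test_that("null loci center below 0 dB and planted loci stand out", {
  sim <- env_fixture()
  counts <- pop_allele_counts(sim$genotypes)
  om <- estimate_omega(counts)
  bf <- bayes_factor_scan(counts, sim$env$BIO12, om)[, 1]
  key <- paste(sim$genotypes$variants$chrom, sim$genotypes$variants$pos)
  planted <- key %in% paste(sim$truth$env_loci$chrom, sim$truth$env_loci$pos)
  expect_lt(median(bf[!planted], na.rm = TRUE), 0)
  expect_gt(mean(bf[planted]), mean(bf[!planted], na.rm = TRUE))
  # most planted loci clear the null 99th percentile
  q99 <- quantile(bf[!planted], 0.99, na.rm = TRUE)
  expect_gte(mean(bf[planted] > q99), 0.5)
})

test_that("the replicate protocol is deterministic and averages correctly", {
  sim <- env_fixture()
  gm <- subset_geno(sim$genotypes, variants = 1:1500)
  covs <- c("BIO12", "BIO5")
  s1 <- run_env_protocol(gm, sim$env, covariates = covs, n_runs = 3,
                         seed = 99, omega_subsample = 800,
                         pruned_idx = 1:1500)
  s2 <- run_env_protocol(gm, sim$env, covariates = covs, n_runs = 3,
                         seed = 99, omega_subsample = 800,
                         pruned_idx = 1:1500)
  expect_identical(s1$bf, s2$bf)
  expect_identical(s1$run_counts, s2$run_counts)
  # n_runs = 1 equals a single direct scan with the same subsample seed
  s3 <- run_env_protocol(gm, sim$env, covariates = covs, n_runs = 1,
                         seed = 99, omega_subsample = 800)
  expect_false(is.null(s3$bf$BIO12_raw))
  # window columns equal brute-force windows of the raw column
  win <- sliding_windows(s1$bf$BIO12_raw, s1$bf$chrom, k = 9)
  expect_equal(s1$bf$BIO12_mean, win$mean)
  expect_equal(s1$bf$BIO12_median, win$median)
  # missing covariate named in the error
  expect_error(run_env_protocol(gm, sim$env[, 1:5], covariates = covs),
               "BIO12")
})

test_that("covariate ranking counts high-BF pruned markers per run", {
  sim <- env_fixture()
  gm <- subset_geno(sim$genotypes, variants = 1:2000)
  scan <- run_env_protocol(gm, sim$env, covariates = c("BIO12", "BIO5"),
                           n_runs = 2, seed = 3, omega_subsample = 1000,
                           pruned_idx = 1:2000, threshold_db = 10)
  r <- rank_covariates(scan)
  expect_setequal(r$covariate, c("BIO12", "BIO5"))
  expect_equal(r$mean_count, sort(colMeans(scan$run_counts),
                                  decreasing = TRUE), ignore_attr = TRUE)
  expect_true(all(r$mean_count <= 2000))
  # protocol without a pruned set cannot rank
  s0 <- run_env_protocol(gm, sim$env, covariates = "BIO5", n_runs = 1,
                         seed = 3, omega_subsample = 1000)
  expect_error(rank_covariates(s0), "pruned")
})

test_that("null BF>10 fraction on a pruned panel is small", {
  sim <- simulate_dataset(sim_config(n_pops = 12, samples_per_pop = 8,
                                     n_snps = 6000, omega_true = 0.02,
                                     seed = 55))  # no planted loci
  gm <- sim$genotypes
  scan <- run_env_protocol(gm, sim$env, covariates = c("BIO3", "BIO14"),
                           n_runs = 2, seed = 8, omega_subsample = 3000,
                           pruned_idx = seq_len(6000), threshold_db = 10)
  frac <- colMeans(scan$run_counts) / 6000
  expect_true(all(frac < 0.05))
})
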