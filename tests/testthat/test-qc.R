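test_that("exact HWE test reproduces hand-derived configurations", {
  # 2 diploids, one of each homozygote: het in {0, 2} with probs {1/3, 2/3}
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)  # monomorphic: no test
  expect_equal(hwe_exact_test(0, 0, 7), 1.0)
})

test_that("exact HWE test matches the full-enumeration oracle up to 20 diploids", {
  set.seed(1)
  # exhaustive over small N, random configurations up to N = 20
  configs <- expand.grid(n0 = 0:4, n1 = 0:4, n2 = 0:4)
  configs <- configs[rowSums(configs) >= 1, ]
  for (N in c(10, 15, 20)) {
    extra <- t(vapply(seq_len(40), function(i) {
      x <- as.vector(stats::rmultinom(1, N, runif(3)))
      x
    }, integer(3)))
    configs <- rbind(configs, setNames(as.data.frame(extra),
                                       c("n0", "n1", "n2")))
  }
  got <- hwe_exact_test(configs$n0, configs$n1, configs$n2)
  want <- mapply(hwe_enum_oracle, configs$n0, configs$n1, configs$n2)
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_true(all(got > 0 & got <= 1))
})

test_that("marker filters remove sites stage by stage with additive counts", {
  # 10 SNPs: 2 low QUAL, 1 with poor call rate, 1 HWE-violating,
  # 1 low MAF, 1 monomorphic
  set.seed(2)
  n <- 40
  g <- sapply(1:10, function(i) rbinom(n, 2, 0.5))
  g[, 3] <- c(rep(NA, 15), rbinom(n - 15, 2, 0.5))        # call rate 0.625
  g[, 4] <- rep(c(0L, 2L), n / 2)                          # no hets: HWE blown
  g[, 5] <- c(1L, rep(0L, n - 1))                          # MAF 1/80
  g[, 7] <- rep(0L, n)                                     # monomorphic
  gm <- make_gm(g, qual = c(30, 35, rep(60, 8)),
                pops = rep(c("popA", "popB"), each = n / 2))
  res <- filter_markers(gm, qc_thresholds())
  rep_df <- res$report
  expect_equal(rep_df$removed[rep_df$stage == "qual"], 2)
  expect_equal(rep_df$removed[rep_df$stage == "call_rate"], 1)
  expect_equal(rep_df$removed[rep_df$stage == "hwe"], 1)
  # the rare-variant column and the monomorphic column both fall at MAF
  expect_equal(rep_df$removed[rep_df$stage == "maf"], 2)
  # additivity: removals sum to input - output
  expect_equal(sum(rep_df$removed), 10 - ncol(res$genotypes$geno))
  # rerunning on own output is a no-op
  res2 <- filter_markers(res$genotypes, qc_thresholds())
  expect_equal(sum(res2$report$removed), 0)
  expect_identical(res2$genotypes$geno, res$genotypes$geno)
})

test_that("MAF boundary is inclusive: 0.05 kept, 0.04 removed", {
  set.seed(4)
  n <- 50  # 100 chromosomes
  mk_col <- function(ac) c(rep(1L, ac), rep(0L, n - ac))
  g <- cbind(mk_col(5), mk_col(4), rbinom(n, 2, 0.5))
  gm <- make_gm(g, pops = rep("popA", n))
  res <- filter_markers(gm, qc_thresholds())
  expect_equal(res$report$removed[res$report$stage == "maf"], 1)
  expect_equal(ncol(res$genotypes$geno), 2)
})

test_that("planted monomorphic sites are all removed at the final stage", {
  sim <- simulate_dataset(sim_config(n_pops = 4, samples_per_pop = 10,
                                     n_snps = 400, omega_true = 0.01,
                                     seed = 17))
  gm <- sim$genotypes
  mono <- sample(ncol(gm$geno), 100)
  gm$geno[, mono] <- 0L
  # relax other filters so only the monomorphism stage acts on the plants
  th <- qc_thresholds(maf_min = 0, hwe_p_min = 1e-300)
  res <- filter_markers(gm, th)
  # every planted site removed, all at the monomorphic stage
  expect_gte(res$report$removed[res$report$stage == "monomorphic"], 100)
  expect_false(any(mono %in% match(res$genotypes$variants$id,
                                   gm$variants$id)))
})

test_that("non-autosomal records are dropped before other filters", {
  g <- matrix(rbinom(40, 2, 0.5), 4)
  gm <- make_gm(g, chrom = c(rep("chr1", 5), "chrX", "chrY", "MT",
                             "chr2", "chr2"))
  res <- suppressMessages(filter_markers(gm, qc_thresholds(maf_min = 0,
                                                           hwe_p_min = 1e-300)))
  expect_equal(res$report$removed[res$report$stage == "autosomes"], 3)
  expect_false(any(res$genotypes$variants$chrom %in% c("chrX", "chrY", "MT")))
})

test_that("LD pruning keeps one of identical columns and respects chromosomes", {
  x <- rbinom(30, 2, 0.5)
  gm <- make_gm(cbind(x, x, x), pos = c(100L, 500L, 900L))
  expect_equal(ld_prune(gm, window_bp = 1000, r2_max = 0.8), 1L)
  # same columns on different chromosomes: never pruned against each other
  gm2 <- make_gm(cbind(x, x), chrom = c("chr1", "chr2"),
                 pos = c(100L, 200L))
  expect_equal(ld_prune(gm2, window_bp = 1e6, r2_max = 0.8), c(1L, 2L))
  # outside the physical window: kept
  gm3 <- make_gm(cbind(x, x), pos = c(100L, 200000L))
  expect_equal(ld_prune(gm3, window_bp = 1000, r2_max = 0.8), c(1L, 2L))
})

test_that("LD pruning matches the brute-force oracle and its post-condition", {
  sim <- simulate_dataset(sim_config(n_pops = 4, samples_per_pop = 12,
                                     n_snps = 200, n_chroms = 2,
                                     chrom_length_bp = 200000,
                                     ld_duplicate_frac = 0.3, seed = 23))
  gm <- sim$genotypes
  gm$geno[sample(length(gm$geno), 100)] <- NA  # exercise pairwise deletion
  kept <- ld_prune(gm, window_bp = 50000, r2_max = 0.5)
  oracle <- ld_prune_bruteforce(gm$geno, gm$variants$chrom, gm$variants$pos,
                                50000, 0.5)
  expect_equal(kept, oracle)
  # post-condition: no retained pair within a window exceeds r2_max
  v <- gm$variants
  for (a in seq_along(kept)) {
    for (b in seq_along(kept)) {
      if (b <= a) next
      i <- kept[a]; j <- kept[b]
      if (v$chrom[i] != v$chrom[j] || v$pos[j] - v$pos[i] > 50000) next
      expect_lte(r2_pair(gm$geno[, i], gm$geno[, j]), 0.5)
    }
  }
})

test_that("zero-variance markers are never pruned for LD", {
  x <- rbinom(20, 2, 0.5)
  gm <- make_gm(cbind(x, rep(1L, 20), x), pos = c(10L, 20L, 30L))
  kept <- ld_prune(gm, window_bp = 1000, r2_max = 0.5)
  expect_true(2L %in% kept)   # constant column survives
  expect_false(3L %in% kept)  # duplicate pruned
})

test_that("KING kinship is 0.5 for duplicates and ~0 for unrelated samples", {
  sim <- simulate_dataset(sim_config(n_pops = 2, samples_per_pop = 6,
                                     n_snps = 4000, omega_true = 0,
                                     seed = 19))
  gm <- sim$genotypes
  gm$geno[1, ] <- gm$geno[2, ]  # make a duplicate pair
  kin <- king_kinship(gm)
  dup <- kin$kinship[kin$id1 == gm$samples[1] & kin$id2 == gm$samples[2]]
  expect_equal(dup, 0.5)
  rest <- kin$kinship[!(kin$id1 == gm$samples[1] & kin$id2 == gm$samples[2])]
  expect_lt(max(abs(rest)), 0.08)
  expect_lt(abs(mean(rest)), 0.03)
})

test_that("KING kinship recovers parent-offspring pairs from Mendelian draws", {
  set.seed(29)
  M <- 12000
  p <- runif(M, 0.2, 0.8)
  n_pairs <- 10
  phis <- vapply(seq_len(n_pairs), function(i) {
    parent <- rbinom(M, 2, p)
    # offspring: one gamete from the parent, one from the population
    gamete_p <- ifelse(parent == 1, rbinom(M, 1, 0.5), parent / 2)
    offspring <- gamete_p + rbinom(M, 1, p)
    gm <- make_gm(rbind(parent, offspring), pops = c("popA", "popA"))
    king_kinship(gm)$kinship
  }, 0)
  expect_equal(mean(phis), 0.25, tolerance = 0.02)
})

test_that("kinship between diverged populations falls at or below zero", {
  sim <- simulate_dataset(sim_config(n_pops = 2, samples_per_pop = 5,
                                     n_snps = 5000, omega_true = 0.1,
                                     seed = 31))
  kin <- king_kinship(sim$genotypes)
  pops <- setNames(sim$genotypes$populations, sim$genotypes$samples)
  cross <- kin$kinship[pops[kin$id1] != pops[kin$id2]]
  expect_lt(mean(cross), 0)
})

test_that("kinship is undefined without heterozygous sites", {
  gm <- make_gm(rbind(c(0L, 2L, 0L), c(2L, 0L, 2L), c(0L, 1L, 2L)))
  expect_warning(kin <- king_kinship(gm), "undefined")
  expect_true(is.na(kin$kinship[kin$id1 == "S1" & kin$id2 == "S2"]))
})

test_that("relative removal breaks pairs and chains greedily", {
  kin <- data.frame(id1 = c("A"), id2 = c("B"), kinship = 0.3)
  rm1 <- drop_relatives(kin, 0.0884)
  expect_length(rm1, 1)
  expect_true(rm1 %in% c("A", "B"))
  # chain A-B, B-C: B has degree 2, removed alone
  kin2 <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"),
                     kinship = c(0.3, 0.2))
  expect_equal(drop_relatives(kin2, 0.0884), "B")
  # below threshold: nobody removed
  expect_length(drop_relatives(kin, 0.5), 0)
})

test_that("after greedy removal no remaining pair exceeds the threshold", {
  sim <- simulate_dataset(sim_config(n_pops = 2, samples_per_pop = 8,
                                     n_snps = 3000, omega_true = 0.01,
                                     seed = 37))
  gm <- sim$genotypes
  # plant a related cluster: 3 copies of sample 1 with small perturbations
  for (i in 2:4) {
    gm$geno[i, ] <- gm$geno[1, ]
    flip <- sample(ncol(gm$geno), 150)
    gm$geno[i, flip] <- rbinom(150, 2, 0.5)
  }
  kin <- king_kinship(gm)
  out <- drop_relatives(kin, 0.0884)
  left <- kin[!(kin$id1 %in% out) & !(kin$id2 %in% out), ]
  expect_true(all(left$kinship <= 0.0884))
  expect_lte(length(out), 3)
})

test_that("per-site diversity counts discordant chromosome pairs", {
  # x = 5 alt alleles among n = 10 chromosomes: pi = 5*5/choose(10,2)
  g <- matrix(c(2L, 2L, 1L, 0L, 0L), 5, 1)
  d <- site_diversity(make_gm(g))
  expect_equal(d$per_site, 25 / 45)
  # monomorphic and fixed-alt sites have pi = 0
  g2 <- cbind(rep(0L, 5), rep(2L, 5))
  expect_equal(site_diversity(make_gm(g2))$per_site, c(0, 0))
  # a single called diploid still has two chromosomes: one het pair
  g3 <- matrix(c(1L, NA, NA, NA, NA), 5, 1)
  expect_equal(site_diversity(make_gm(g3))$per_site, 1)
  # no called chromosomes: skipped
  g4 <- matrix(NA_integer_, 5, 1)
  expect_true(is.na(site_diversity(make_gm(g4))$per_site))
})
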