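#' Simulation configuration
#'
#' Describes a synthetic multi-population SNP dataset with a known covariance
#' structure of population allele frequencies (the omega matrix of the
#' association model), optional loci whose frequencies track an environmental
#' covariate, and optional loci with a branch-specific frequency shift in a
#' designated subset of populations. The planted loci give every downstream
#' scan a ground truth to recover.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop integer vector (recycled) of diploid sample counts.
#' @param n_snps total number of SNPs.
#' @param n_chroms number of chromosomes; SNP positions are drawn uniformly
#'   per chromosome and sorted.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param omega_true P x P positive-semidefinite covariance matrix of
#'   standardized population allele frequencies; a scalar is expanded to
#'   `scalar * I`.
#' @param env_loci named integer vector: covariate name -> number of planted
#'   environment-associated loci for that covariate.
#' @param beta_env effect size in standardized-frequency units per covariate
#'   standard deviation, applied at planted environment loci.
#' @param n_branch_loci number of loci receiving a branch-specific shift.
#' @param branch_shift allele-frequency displacement (0 < shift < 1) added in
#'   the populations listed in `shifted_pops`.
#' @param shifted_pops indices of populations receiving the branch shift.
#' @param ld_duplicate_frac fraction of SNPs duplicated next to their template
#'   with a small amount of genotype noise, creating near-perfect-r2 pairs for
#'   exercising LD pruning (0 disables; no linkage is simulated otherwise).
#' @param seed integer seed controlling every random draw.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 12,
                       samples_per_pop = 8,
                       n_snps = 5000,
                       n_chroms = 5,
                       chrom_length_bp = 5e7,
                       omega_true = 0.02,
                       env_loci = c(BIO12 = 0),
                       beta_env = 0.25,
                       n_branch_loci = 0,
                       branch_shift = 0.4,
                       shifted_pops = seq_len(min(3, n_pops)),
                       ld_duplicate_frac = 0,
                       seed = 1L) {
  if (length(omega_true) == 1L)
    omega_true <- diag(as.numeric(omega_true), n_pops)
  omega_true <- as.matrix(omega_true)
  if (nrow(omega_true) != n_pops || ncol(omega_true) != n_pops)
    stop("omega_true must be ", n_pops, " x ", n_pops)
  if (max(abs(omega_true - t(omega_true))) > 1e-10)
    stop("omega_true must be symmetric")
  ev <- eigen(omega_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("omega_true is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  stopifnot(all(samples_per_pop >= 1L), n_snps >= 1L, n_chroms >= 1L,
            beta_env >= 0, n_branch_loci >= 0,
            branch_shift > 0, branch_shift < 1,
            all(env_loci >= 0),
            all(shifted_pops >= 1L), all(shifted_pops <= n_pops),
            ld_duplicate_frac >= 0, ld_duplicate_frac < 1)
  if (is.null(names(env_loci)) && any(env_loci > 0))
    stop("env_loci must be a named vector (covariate name -> locus count)")
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 n_snps = as.integer(n_snps), n_chroms = as.integer(n_chroms),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 omega_true = omega_true, env_loci = env_loci,
                 beta_env = beta_env,
                 n_branch_loci = as.integer(n_branch_loci),
                 branch_shift = branch_shift,
                 shifted_pops = as.integer(shifted_pops),
                 ld_duplicate_frac = ld_duplicate_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# matrix square root for a PSD covariance (chol fails on rank-deficient input)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Names of the environmental covariates
#'
#' Altitude plus the 19 standard bioclimatic variables BIO1-BIO19.
#' @return Character vector of length 20.
#' @export
covariate_names <- function() c("altitude", paste0("BIO", 1:19))

# Covariates fall in two correlated blocks: a temperature/altitude block
# (altitude loads negatively: high sites are cold) and a precipitation block,
# plus weakly loaded seasonality variables, emulating the usual two-axis
# structure of WorldClim tables without copying real values.
simulate_env_table <- function(n_pops) {
  f_temp <- stats::rnorm(n_pops)
  f_prec <- stats::rnorm(n_pops)
  temp_block <- c("BIO1", "BIO5", "BIO6", "BIO8", "BIO9", "BIO10", "BIO11")
  prec_block <- c("BIO12", "BIO13", "BIO14", "BIO16", "BIO17", "BIO18", "BIO19")
  load_of <- function(v) {
    if (v == "altitude") c(-0.85, 0)
    else if (v %in% temp_block) c(0.85, 0)
    else if (v %in% prec_block) c(0, 0.85)
    else c(0.3, 0.3)  # BIO2/3/4/7/15: diurnal range & seasonality, mixed
  }
  env <- data.frame(location = paste0("pop", seq_len(n_pops)),
                    latitude = stats::runif(n_pops, 5, 15),
                    longitude = stats::runif(n_pops, 35, 45))
  for (v in covariate_names()) {
    l <- load_of(v)
    resid <- sqrt(max(1 - sum(l^2), 0.05))
    env[[v]] <- l[1] * f_temp + l[2] * f_prec + resid * stats::rnorm(n_pops)
  }
  env
}

#' Simulate a multi-population SNP dataset with planted truth
#'
#' Ancestral frequencies are drawn uniformly on (0.05, 0.95); per-SNP
#' standardized population deviations are multivariate normal with covariance
#' `omega_true`; population frequencies are
#' `clamp(pi + a * sqrt(pi (1 - pi)), 0.001, 0.999)`. Environment-associated
#' loci add `beta_env * Z_j` to the standardized deviation of population `j`
#' (`Z` the standardized covariate); branch loci add `branch_shift` to the
#' frequency in the designated populations only. Genotypes are binomial
#' draws of two alleles at the population frequency.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()]), `env`
#'   (location x covariate data.frame) and `truth` (planted loci: `env_loci`
#'   data.frame (covariate, chrom, pos, beta), `branch_loci` data.frame
#'   (chrom, pos, shifted_pops), `ancestral_freqs`, `pop_freqs`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  P <- config$n_pops
  M <- config$n_snps

  env <- simulate_env_table(P)

  # genome layout: uniform positions, sorted within chromosome
  chrom <- sort(sample.int(config$n_chroms, M, replace = TRUE))
  pos <- integer(M)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(config$chrom_length_bp, length(idx)))
  }
  chrom_lab <- paste0("chr", chrom)

  pi_anc <- stats::runif(M, 0.05, 0.95)
  A <- psd_sqrt(config$omega_true)
  alpha_star <- matrix(stats::rnorm(M * P), M, P) %*% A  # M x P deviations

  # plant environment-associated loci on non-overlapping SNP sets
  taken <- integer(0)
  env_truth <- list()
  for (cov in names(config$env_loci)) {
    k <- config$env_loci[[cov]]
    if (k == 0) next
    if (!cov %in% names(env)) stop("unknown covariate in env_loci: ", cov)
    free <- setdiff(seq_len(M), taken)
    loci <- sort(sample(free, k))
    taken <- c(taken, loci)
    z <- as.numeric(scale(env[[cov]]))
    alpha_star[loci, ] <- alpha_star[loci, ] +
      config$beta_env * matrix(z, k, P, byrow = TRUE)
    env_truth[[cov]] <- data.frame(covariate = cov, chrom = chrom_lab[loci],
                                   pos = pos[loci], beta = config$beta_env)
  }
  env_truth <- if (length(env_truth)) do.call(rbind, env_truth) else
    data.frame(covariate = character(), chrom = character(),
               pos = integer(), beta = numeric())
  rownames(env_truth) <- NULL

  freq <- pi_anc + alpha_star * sqrt(pi_anc * (1 - pi_anc))

  # branch-shifted loci: frequency displacement in the designated pops only
  branch_truth <- data.frame(chrom = character(), pos = integer(),
                             shifted_pops = character())
  if (config$n_branch_loci > 0) {
    free <- setdiff(seq_len(M), taken)
    bl <- sort(sample(free, config$n_branch_loci))
    freq[bl, config$shifted_pops] <- freq[bl, config$shifted_pops] +
      config$branch_shift
    branch_truth <- data.frame(chrom = chrom_lab[bl], pos = pos[bl],
                               shifted_pops = paste(config$shifted_pops,
                                                    collapse = ","))
  }

  n_clamped <- sum(freq < 0.001 | freq > 0.999)
  if (n_clamped > 0.10 * length(freq))
    warning(sprintf("frequency clamp hit on %.1f%% of population frequencies",
                    100 * n_clamped / length(freq)))
  freq <- pmin(pmax(freq, 0.001), 0.999)

  n_samples <- sum(config$samples_per_pop)
  pops <- rep(paste0("pop", seq_len(P)), config$samples_per_pop)
  geno <- matrix(0L, n_samples, M)
  row0 <- 0L
  for (j in seq_len(P)) {
    nj <- config$samples_per_pop[j]
    geno[row0 + seq_len(nj), ] <- matrix(
      stats::rbinom(nj * M, 2L, rep(freq[, j], each = nj)), nj, M)
    row0 <- row0 + nj
  }
  rownames(geno) <- sprintf("%s_ind%d", pops,
                            unlist(lapply(config$samples_per_pop, seq_len)))

  variants <- data.frame(chrom = chrom_lab, pos = pos,
                         id = paste0("snp", seq_len(M)),
                         ref = "A", alt = "G", qual = 60)

  gm <- geno_matrix(geno, variants, pops)
  if (config$ld_duplicate_frac > 0)
    gm <- add_ld_duplicates(gm, config$ld_duplicate_frac)

  truth <- list(env_loci = env_truth, branch_loci = branch_truth,
                ancestral_freqs = pi_anc, pop_freqs = freq)
  list(genotypes = gm, env = env, truth = truth)
}

# Duplicate a fraction of SNPs immediately downstream of their template with
# a little genotype noise, creating r^2 ~ 1 pairs for LD-pruning tests.
add_ld_duplicates <- function(gm, frac, noise_rate = 0.02) {
  M <- ncol(gm$geno)
  k <- max(1L, round(frac * M))
  src <- sort(sample.int(M, k))
  dup <- gm$geno[, src, drop = FALSE]
  flip <- matrix(stats::runif(length(dup)) < noise_rate, nrow(dup))
  dup[flip] <- sample(0:2, sum(flip), replace = TRUE)
  v <- gm$variants
  vd <- v[src, , drop = FALSE]
  vd$pos <- vd$pos + 1L
  vd$id <- paste0(vd$id, "_dup")
  geno <- cbind(gm$geno, dup)
  vv <- rbind(v, vd)
  o <- order(vv$chrom, vv$pos)
  geno_matrix(geno[, o, drop = FALSE], vv[o, , drop = FALSE], gm$populations)
}

#' Generate a non-overlapping gene annotation for a simulated genome
#'
#' Tiles each chromosome with genes of fixed length separated by gaps, in
#' 0-based half-open coordinates (BED convention).
#'
#' @param config a [sim_config()].
#' @param n_genes_per_chrom genes per chromosome.
#' @param gene_length_bp gene length in bp.
#' @return data.frame (chrom, start, end, strand, symbol).
#' @export
simulate_annotation <- function(config, n_genes_per_chrom = 50,
                                gene_length_bp = 20000) {
  span <- config$chrom_length_bp
  if (n_genes_per_chrom * gene_length_bp > span)
    stop("genes do not fit on the chromosome")
  step <- span %/% n_genes_per_chrom
  starts <- (seq_len(n_genes_per_chrom) - 1L) * step
  out <- do.call(rbind, lapply(seq_len(config$n_chroms), function(cc) {
    data.frame(chrom = paste0("chr", cc),
               start = starts,
               end = starts + gene_length_bp,
               strand = rep_len(c("+", "-"), n_genes_per_chrom),
               symbol = sprintf("GENE%d_%03d", cc, seq_len(n_genes_per_chrom)))
  }))
  rownames(out) <- NULL
  out
}
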