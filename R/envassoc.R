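#' Estimate the omega matrix of population allele-frequency covariances
#'
#' Moment estimator of the association model's null correlation structure.
#' For each polymorphic SNP the pooled frequency `p` is computed and each
#' population's standardized deviation `u_j = (p_j - p) / sqrt(p (1 - p))`;
#' omega is the sample covariance of `u` across SNPs, shrunk towards its
#' diagonal by `lambda` to guarantee positive definiteness:
#' `omega = (1 - lambda) S + lambda diag(S)`.
#'
#' @param counts a [pop_allele_counts()] object with >= 4 populations.
#' @param snp_idx optional SNP subsample (indices) to estimate from.
#' @param lambda diagonal shrinkage weight; doubled with a warning if the
#'   shrunk matrix is still not positive definite.
#' @param min_snps minimum polymorphic SNPs required.
#' @return list of class `omega_matrix`: `omega` (P x P), `populations`.
#' @export
estimate_omega <- function(counts, snp_idx = NULL, lambda = 0.05,
                           min_snps = 1000L) {
  stopifnot(inherits(counts, "pop_counts"))
  P <- nrow(counts$ac)
  if (P < 4) stop("omega estimation needs >= 4 populations")
  su <- standardized_freqs(counts, snp_idx)
  ok <- colSums(is.finite(su$u)) == P
  if (sum(ok) < min_snps)
    stop("omega estimation needs >= ", min_snps, " polymorphic SNPs, got ",
         sum(ok))
  S <- stats::cov(t(su$u[, ok, drop = FALSE]))
  # S is always singular in one direction (deviations are centered on the
  # pooled frequency), so diagonal shrinkage is required, not optional.
  for (i in 1:20) {
    omega <- (1 - lambda) * S + lambda * diag(diag(S), P)
    if (inherits(try(chol(omega), silent = TRUE), "matrix")) break
    lambda <- max(min(1, lambda * 2), 0.01)
    warning("omega not positive definite; shrinkage increased to ", lambda)
  }
  structure(list(omega = omega, populations = rownames(counts$ac),
                 lambda = lambda),
            class = "omega_matrix")
}

# Standardized sample frequencies and their sampling variances.
# u: P x M with NaN where the pooled site is monomorphic; d: P x M binomial
# variance of p_hat_j rescaled by the pooled p(1-p) (the diagonal noise term
# of the Gaussian observation model).
standardized_freqs <- function(counts, snp_idx = NULL) {
  ac <- counts$ac; an <- counts$an
  if (!is.null(snp_idx)) {
    ac <- ac[, snp_idx, drop = FALSE]
    an <- an[, snp_idx, drop = FALSE]
  }
  p_hat <- ac / an                                 # P x M (NaN where an = 0)
  pool <- colSums(ac) / colSums(an)
  pq <- pool * (1 - pool)
  pq[pq == 0] <- NA_real_                          # monomorphic -> undefined
  u <- sweep(p_hat, 2, pool, "-")
  u <- sweep(u, 2, sqrt(pq), "/")
  d <- sweep(p_hat * (1 - p_hat) / an, 2, pq, "/")
  d[!is.finite(d)] <- NA_real_
  list(u = u, d = d, pooled = pool)
}

#' Bayes factors for genotype-environment association
#'
#' Gaussian approximation of the standardized-covariate association model:
#' the vector of standardized sample frequencies at a SNP is modelled as
#' `Normal(beta Z, omega + D)` where `Z` is the standardized covariate, omega
#' the population covariance and `D` the diagonal binomial sampling variance
#' (per-population chromosome counts). The marginal likelihood under
#' association integrates `beta` over a uniform prior by fixed-grid
#' quadrature; the null fixes `beta = 0`. Returned on the deciban scale,
#' `10 log10(BF)`.
#'
#' @param counts a [pop_allele_counts()] object.
#' @param Z covariate matrix (populations x covariates) or vector, in the
#'   row order of `counts`; standardized internally to zero mean and unit
#'   variance.
#' @param omega an [estimate_omega()] result (or bare P x P matrix).
#' @param prior_beta uniform prior bounds on the effect size.
#' @param n_grid quadrature nodes.
#' @return matrix SNPs x covariates of Bayes factors in dB; `NA` at sites
#'   monomorphic across all populations.
#' @export
bayes_factor_scan <- function(counts, Z, omega, prior_beta = c(-0.3, 0.3),
                              n_grid = 201L) {
  stopifnot(inherits(counts, "pop_counts"))
  om <- if (inherits(omega, "omega_matrix")) omega$omega else as.matrix(omega)
  Z <- as.matrix(Z)
  P <- nrow(counts$ac)
  stopifnot(nrow(Z) == P, nrow(om) == P, ncol(om) == P)
  sds <- apply(Z, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("covariate has zero variance: ",
         paste(colnames(Z)[!is.finite(sds) | sds == 0], collapse = ", "))
  Zs <- scale(Z)
  su <- standardized_freqs(counts)
  u <- su$u; d <- su$d
  bad <- !is.finite(u) | !is.finite(d)
  u[bad] <- NaN
  d[bad] <- 0
  grid <- seq(prior_beta[1], prior_beta[2], length.out = n_grid)
  bf <- bf_db_kernel(u, d, om, Zs, grid)
  colnames(bf) <- colnames(Z)
  bf
}

#' Replicated environmental-association protocol
#'
#' Runs the Bayes-factor scan `n_runs` times per covariate. Replicates
#' differ only through the omega matrix, re-estimated in each run from a
#' fresh random SNP subsample (mirroring the between-run variability that
#' sampler-based implementations average over); per-SNP Bayes factors are
#' averaged arithmetically on the dB scale across runs. When a pruned
#' marker set is supplied, the per-run count of pruned markers with
#' `BF > threshold_db` is recorded per covariate for [rank_covariates()].
#'
#' @param gm a QC-passed [geno_matrix()].
#' @param env environment table (one row per population; `location` must
#'   match population labels).
#' @param covariates covariate columns to scan.
#' @param n_runs replicate runs.
#' @param seed integer; expands deterministically into per-run seeds.
#' @param omega_subsample SNPs per omega-estimation subsample.
#' @param prior_beta,n_grid passed to [bayes_factor_scan()].
#' @param lambda omega shrinkage.
#' @param pruned_idx optional variant indices (the LD-pruned comparison set)
#'   on which `BF > threshold_db` markers are counted per run.
#' @param threshold_db deciban threshold for counting (default 10,
#'   conventionally "strong evidence").
#' @param k sliding-window size for BF window statistics.
#' @return list of class `env_scan`: `bf` data.frame with chrom, pos and,
#'   per covariate, `<cov>_raw` (run-averaged dB), `<cov>_mean`,
#'   `<cov>_median` (9-SNP windows of the run average); `run_counts`
#'   (n_runs x covariates, or NULL); `pruned_idx`, `n_runs`, `covariates`.
#' @export
run_env_protocol <- function(gm, env, covariates = covariate_names(),
                             n_runs = 100L, seed = 1L,
                             omega_subsample = 50000L,
                             prior_beta = c(-0.3, 0.3), n_grid = 201L,
                             lambda = 0.05, pruned_idx = NULL,
                             threshold_db = 10, k = 9) {
  stopifnot(inherits(gm, "geno_matrix"), n_runs >= 1)
  missing_cov <- setdiff(covariates, names(env))
  if (length(missing_cov))
    stop("environment table lacks covariate(s): ",
         paste(missing_cov, collapse = ", "))
  counts <- pop_allele_counts(gm)
  pops <- rownames(counts$ac)
  if (!all(pops %in% env$location))
    stop("environment table lacks rows for population(s): ",
         paste(setdiff(pops, env$location), collapse = ", "))
  Z <- as.matrix(env[match(pops, env$location), covariates, drop = FALSE])
  rownames(Z) <- pops

  M <- ncol(counts$ac)
  poly <- which(colSums(counts$ac) > 0 & colSums(counts$ac) < colSums(counts$an))
  n_sub <- min(omega_subsample, length(poly))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)

  bf_sum <- NULL
  run_counts <- if (!is.null(pruned_idx))
    matrix(NA_real_, n_runs, length(covariates),
           dimnames = list(NULL, covariates)) else NULL
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    idx <- if (n_sub < length(poly)) sort(sample(poly, n_sub)) else poly
    omega <- estimate_omega(counts, snp_idx = idx, lambda = lambda,
                            min_snps = min(1000L, n_sub))
    bf <- bayes_factor_scan(counts, Z, omega, prior_beta, n_grid)
    if (is.null(bf_sum)) bf_sum <- bf else bf_sum <- bf_sum + bf
    if (!is.null(pruned_idx))
      run_counts[r, ] <- colSums(bf[pruned_idx, , drop = FALSE] > threshold_db,
                                 na.rm = TRUE)
  }
  bf_mean <- bf_sum / n_runs

  out <- data.frame(chrom = counts$variants$chrom, pos = counts$variants$pos)
  for (cv in covariates) {
    out[[paste0(cv, "_raw")]] <- bf_mean[, cv]
    win <- sliding_windows(bf_mean[, cv], out$chrom, k = k)
    out[[paste0(cv, "_mean")]] <- win$mean
    out[[paste0(cv, "_median")]] <- win$median
  }
  structure(list(bf = out, run_counts = run_counts, pruned_idx = pruned_idx,
                 n_runs = n_runs, covariates = covariates,
                 threshold_db = threshold_db),
            class = "env_scan")
}

#' @export
print.env_scan <- function(x, ...) {
  cat(sprintf("env_scan: %d SNPs x %d covariates, %d run(s)\n",
              nrow(x$bf), length(x$covariates), x$n_runs))
  invisible(x)
}

#' Rank covariates by their average count of high-Bayes-factor markers
#'
#' Per covariate and per replicate run, counts the LD-pruned markers with a
#' Bayes factor above the threshold, then averages counts across runs and
#' sorts descending. This ranks environmental variables by the strength of
#' their genome-wide association signal.
#'
#' @param scan an [run_env_protocol()] result produced with a non-NULL
#'   `pruned_idx`.
#' @return data.frame (covariate, mean_count) sorted descending, with the
#'   per-run count matrix attached as attribute `run_counts`.
#' @export
rank_covariates <- function(scan) {
  stopifnot(inherits(scan, "env_scan"))
  if (is.null(scan$run_counts))
    stop("protocol was run without a pruned marker set; ",
         "pass pruned_idx to run_env_protocol()")
  mc <- colMeans(scan$run_counts)
  out <- data.frame(covariate = names(mc), mean_count = unname(mc))
  out <- out[order(-out$mean_count, out$covariate), ]
  rownames(out) <- NULL
  attr(out, "run_counts") <- scan$run_counts
  out
}
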