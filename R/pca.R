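#' Principal components of the environment table
#'
#' Covariates are centered and scaled to unit variance, then decomposed by
#' SVD; variance fractions are squared singular values over their total.
#' Constant covariates are dropped with a warning. Each component is
#' oriented so its largest-magnitude loading is positive (the SVD sign is
#' arbitrary).
#'
#' @param env environment table (one row per location).
#' @param covariates covariate columns to use.
#' @return list of class `pca_result`: `scores` (locations x components),
#'   `loadings` (covariates x components), `variance_explained`.
#' @export
env_pca <- function(env, covariates = covariate_names()) {
  stopifnot(nrow(env) >= 3, all(covariates %in% names(env)))
  X <- as.matrix(env[, covariates, drop = FALSE])
  rownames(X) <- if (!is.null(env$location)) env$location else rownames(env)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant covariate(s) dropped: ",
            paste(covariates[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pca_of(scale(X))
}

#' Principal components of a genotype matrix
#'
#' Population-structure PCA: missing dosages are mean-imputed per SNP,
#' columns centered and scaled by `sqrt(2 p (1 - p))` with `p` the sample
#' allele frequency, and the sample x SNP matrix decomposed by SVD.
#' Monomorphic SNPs are skipped.
#'
#' @param gm a [geno_matrix()] (typically QC-passed).
#' @param n_components components to retain (default all).
#' @return list of class `pca_result` with per-sample `scores`, per-SNP
#'   `loadings` and `variance_explained`.
#' @export
genotype_pca <- function(gm, n_components = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  G <- gm$geno
  storage.mode(G) <- "double"
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- 2 * p[j]
  X <- sweep(G, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  pca_of(X, n_components)
}

pca_of <- function(X, n_components = NULL) {
  k_max <- min(dim(X))
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  if (!is.null(n_components) && n_components > k_max)
    warning("requested ", n_components, " components; rank allows ", k_max)
  sv <- svd(X, nu = k, nv = k)
  # orient: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = sv$d^2 / sum(sv$d^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("pca_result: %d x %d scores; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * ve[seq_len(min(5, length(ve)))]),
                    collapse = ", ")))
  invisible(x)
}
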