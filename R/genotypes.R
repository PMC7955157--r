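#' Genotype matrix container
#'
#' Bundles a samples x variants matrix of diploid genotype dosages (0 =
#' homozygous reference, 1 = heterozygous, 2 = homozygous alternate, `NA` =
#' missing) with per-variant records and per-sample population labels. This is
#' the common currency passed between the QC, differentiation, association and
#' PCA stages.
#'
#' @param geno integer matrix, samples in rows, variants in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`; one row per column of `geno`, sorted by (`chrom`, `pos`).
#' @param populations character vector of population labels, one per sample.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, variants, populations) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos") %in% names(variants)))
  if (nrow(variants) != ncol(geno))
    stop("variants must have one row per genotype column")
  if (length(populations) != nrow(geno))
    stop("populations must have one label per sample")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  for (col in c("id", "ref", "alt")) {
    if (is.null(variants[[col]]))
      variants[[col]] <- switch(col, id = paste0("snp", seq_len(nrow(variants))),
                                ref = "A", alt = "G")
  }
  if (is.null(variants$qual)) variants$qual <- 60
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  structure(list(geno = geno,
                 variants = variants,
                 samples = rownames(geno),
                 populations = as.character(populations)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants, %d populations\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$populations))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.2f%%; chromosomes: %s\n", 100 * miss,
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param samples logical/integer/character index of samples to keep.
#' @param variants logical/integer index of variants to keep.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$geno
  pops <- gm$populations
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$samples)
    g <- g[samples, , drop = FALSE]
    pops <- pops[samples]
  }
  v <- gm$variants
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  geno_matrix(g, v, pops)
}

#' Per-population allele and genotype-class counts
#'
#' For each population (or pooled group of populations) and each variant,
#' counts alternate alleles, called chromosomes and the three genotype classes.
#' These counts are the sufficient statistics consumed by the F_ST, PBS and
#' environmental-association estimators.
#'
#' @param gm a [geno_matrix()].
#' @param groups optional named list mapping a group name to the population
#'   labels pooled into it; defaults to one group per population.
#' @return A list of class `pop_counts` with matrices (`groups` x variants):
#'   `ac` (alt-allele count), `an` (called chromosomes), `n_homref`, `n_het`,
#'   `n_homalt`, plus the variant table.
#' @export
pop_allele_counts <- function(gm, groups = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(groups)) {
    lv <- unique(gm$populations)
    groups <- stats::setNames(as.list(lv), lv)
  }
  nm <- names(groups)
  M <- ncol(gm$geno)
  mk <- function() matrix(0L, nrow = length(groups), ncol = M,
                          dimnames = list(nm, NULL))
  ac <- mk(); an <- mk(); n0 <- mk(); n1 <- mk(); n2 <- mk()
  for (i in seq_along(groups)) {
    rows <- gm$populations %in% groups[[i]]
    if (!any(rows)) stop("group '", nm[i], "' matches no samples")
    g <- gm$geno[rows, , drop = FALSE]
    n0[i, ] <- colSums(g == 0L, na.rm = TRUE)
    n1[i, ] <- colSums(g == 1L, na.rm = TRUE)
    n2[i, ] <- colSums(g == 2L, na.rm = TRUE)
    an[i, ] <- 2L * (n0[i, ] + n1[i, ] + n2[i, ])
    ac[i, ] <- n1[i, ] + 2L * n2[i, ]
  }
  structure(list(ac = ac, an = an, n_homref = n0, n_het = n1, n_homalt = n2,
                 variants = gm$variants, groups = groups),
            class = "pop_counts")
}

#' @export
print.pop_counts <- function(x, ...) {
  cat(sprintf("pop_counts: %d groups x %d variants\n",
              nrow(x$ac), ncol(x$ac)))
  invisible(x)
}
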