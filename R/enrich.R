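#' Hypergeometric candidate-gene enrichment
#'
#' Tests whether a query gene set (e.g. genes overlapping top-quantile
#' SNPs) is enriched for a candidate list (e.g. high-altitude or
#' hypoxia-response genes). The p-value is the exact upper tail of the
#' hypergeometric distribution, `P(X >= k)` for `X ~ Hypergeom(N, K, n)`
#' with `k` overlaps between the size-`n` query and the size-`K` candidate
#' list drawn from a universe of `N` genes. Fold enrichment is the observed
#' overlap over its expectation, `k / (n K / N)`. Symbols containing "ORF"
#' are excluded from both lists before testing (their function is treated
#' as unknown); matching is case-insensitive.
#'
#' @param query_genes character vector of query gene symbols.
#' @param candidate_genes character vector of candidate symbols.
#' @param universe_size total genes `N` in the universe (the candidate list
#'   is assumed drawn from it).
#' @param drop_orf exclude symbols containing "ORF" from both lists.
#' @return list of class `enrichment_result`: `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `overlap` (the overlapping symbols), plus `n_raw`/`K_raw`
#'   (sizes before ORF removal).
#' @export
hypergeom_enrich <- function(query_genes, candidate_genes,
                             universe_size = 13510L, drop_orf = TRUE) {
  q_raw <- unique(toupper(trimws(query_genes)))
  c_raw <- unique(toupper(trimws(candidate_genes)))
  q <- q_raw; cand <- c_raw
  if (drop_orf) {
    q <- q[!grepl("ORF", q)]
    cand <- cand[!grepl("ORF", cand)]
  }
  n <- length(q); K <- length(cand); N <- universe_size
  if (n > N || K > N)
    stop("query (", n, ") and candidate (", K,
         ") sizes must not exceed the universe (", N, ")")
  ov <- intersect(q, cand)
  k <- length(ov)
  if (n == 0) {
    res <- list(k = 0L, n = 0L, K = K, N = N, fold = 0, p_value = 1,
                overlap = character(0))
  } else {
    res <- list(k = k, n = n, K = K, N = N,
                fold = k / (n * K / N),
                p_value = hyper_upper_tail(k, N, K, n),
                overlap = sort(ov))
  }
  res$n_raw <- length(q_raw); res$K_raw <- length(c_raw)
  structure(res, class = "enrichment_result")
}

# Exact upper tail P(X >= k), X ~ Hypergeom(N total, K successes, n draws).
hyper_upper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: k=%d of n=%d (K=%d, N=%d)\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  fold = %.2f, p = %.3g\n", x$fold, x$p_value))
  invisible(x)
}

#' Enrichment report across tiers and candidate lists
#'
#' Runs [hypergeom_enrich()] for every combination of test x tier gene set
#' in an outlier catalogue against each candidate list, reporting overlap
#' counts, fold enrichment, p-values and the overlapping symbols. Tiers
#' whose query set is smaller than `min_genes` are flagged as too small to
#' assess.
#'
#' @param catalog result of [catalog_outlier_genes()].
#' @param candidates named list of candidate symbol vectors.
#' @param tests tests (statistic prefixes) to report.
#' @param tiers tiers to report.
#' @param variant statistic variant to use (default the pooled set).
#' @param flank flank in bp.
#' @param universe_size universe gene count `N`.
#' @param min_genes minimum query size considered testable.
#' @return data.frame (candidate, test, tier, k, n, K, N, fold, p_value,
#'   testable, overlap).
#' @export
overlap_report <- function(catalog, candidates, tests,
                           tiers = c(1e-4, 1e-3), variant = "pooled",
                           flank = 0, universe_size = 13510L,
                           min_genes = 10L) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  rows <- list()
  for (cl in names(candidates)) {
    for (test in tests) {
      for (tier in tiers) {
        genes <- tier_gene_set(catalog, test, variant, tier, flank)
        e <- hypergeom_enrich(genes, candidates[[cl]], universe_size)
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = cl, test = test, tier = tier,
          k = e$k, n = e$n, K = e$K, N = e$N,
          fold = e$fold, p_value = e$p_value,
          testable = e$n >= min_genes,
          overlap = paste(e$overlap, collapse = ","))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
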