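#' Select the top fraction of SNPs by a statistic
#'
#' Takes the `m = ceiling(fraction * M)` largest defined values (`M` = number
#' of defined values); ties at the cutoff are all included, so the set may
#' exceed `m`.
#'
#' @param values per-SNP statistic (`NA` = undefined, excluded from both the
#'   count and the selection).
#' @param fraction top proportion, in (0, 1).
#' @return integer indices (into `values`) of the selected SNPs.
#' @export
top_fraction <- function(values, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  def <- which(!is.na(values))
  if (!length(def)) stop("no defined values to rank")
  m <- ceiling(fraction * length(def))
  cutoff <- sort(values[def], decreasing = TRUE)[m]
  def[values[def] >= cutoff]
}

#' Genes overlapping or near a set of SNPs
#'
#' With `flank_bp = 0`, genes whose interval (0-based half-open) contains
#' the SNP position; with a positive flank, genes whose interval expanded by
#' `flank_bp` on both sides contains it (i.e. genes less than `flank_bp`
#' from the SNP). Overlap is strand-agnostic. Implemented on GenomicRanges.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based SNP positions, as
#'   in a VCF).
#' @param genes data.frame (chrom, start, end, symbol), 0-based half-open as
#'   from [read_annotation()].
#' @param flank_bp symmetric expansion of gene intervals in bp.
#' @return character vector of unique gene symbols.
#' @export
genes_near_snps <- function(snps, genes, flank_bp = 0) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)),
            all(c("chrom", "start", "end", "symbol") %in% names(genes)))
  if (nrow(snps) == 0 || nrow(genes) == 0) return(character(0))
  missing_chr <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(missing_chr))
    message("no annotation for chromosome(s): ",
            paste(missing_chr, collapse = ", "))
  # genes: 0-based half-open [start, end) -> 1-based closed [start+1, end];
  # expanded by flank - 1 so "less than flank_bp away" is inclusive of
  # distance flank_bp - 1 and exclusive of flank_bp exactly.
  pad <- if (flank_bp > 0) flank_bp - 1L else 0L
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start + 1L - pad, 1L), genes$end + pad))
  gr_snps <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
  # disjoint seqlevels are expected (already reported above), not a warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_snps, gr_genes))
  unique(genes$symbol[S4Vectors::subjectHits(hits)])
}

#' Pool gene sets across statistic variants
#'
#' Union of the gene symbols found for the raw, window-mean and
#' window-median variants of one test at a common tier and flank.
#'
#' @param ... character vectors of gene symbols (typically three).
#' @return character vector, deduplicated union.
#' @export
pool_variants <- function(...) unique(unlist(list(...), use.names = FALSE))

#' Catalogue outlier genes per test, variant, tier and flank
#'
#' For every statistic column of a scan table, selects the top-`tier`
#' fraction of SNPs and records the genes overlapping them (and within the
#' flank distances), plus the pooled (raw + mean + median) gene set per
#' test. Tier sets are nested by construction.
#'
#' @param scan data.frame with `chrom`, `pos` and one column per statistic
#'   (e.g. `pbs_raw`, `pbs_mean`, `pbs_median`, `altitude_raw`, ...).
#' @param genes annotation data.frame (chrom, start, end, symbol).
#' @param tiers top fractions to catalogue.
#' @param flanks flank distances in bp (0 = direct overlap).
#' @param stat_cols statistic columns; defaults to all numeric columns
#'   except `pos`.
#' @return data.frame (test, variant, tier, flank, symbol); `variant` is
#'   `raw`/`mean`/`median` or `pooled`. Tests without a `_raw`/`_mean`/
#'   `_median` suffix are treated as a single `raw` variant.
#' @export
catalog_outlier_genes <- function(scan, genes,
                                  tiers = c(1e-5, 1e-4, 1e-3),
                                  flanks = c(0, 100000L),
                                  stat_cols = NULL) {
  if (is.null(stat_cols))
    stat_cols <- setdiff(names(scan)[vapply(scan, is.numeric, TRUE)], "pos")
  parse_col <- function(cn) {
    m <- regmatches(cn, regexec("^(.*)_(raw|mean|median)$", cn))[[1]]
    if (length(m)) c(m[2], m[3]) else c(cn, "raw")
  }
  rows <- list()
  for (cn in stat_cols) {
    tv <- parse_col(cn)
    for (tier in tiers) {
      idx <- top_fraction(scan[[cn]], tier)
      snps <- scan[idx, c("chrom", "pos")]
      for (fl in flanks) {
        syms <- genes_near_snps(snps, genes, flank_bp = fl)
        if (length(syms))
          rows[[length(rows) + 1L]] <-
            data.frame(test = tv[1], variant = tv[2], tier = tier,
                       flank = fl, symbol = syms)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(), variant = character(), tier = numeric(),
               flank = numeric(), symbol = character())
  # pooled sets: union over variants per test x tier x flank
  if (nrow(out)) {
    pooled <- unique(out[c("test", "tier", "flank", "symbol")])
    pooled$variant <- "pooled"
    out <- rbind(out, pooled[names(out)])
  }
  rownames(out) <- NULL
  out
}

#' Extract one gene set from an outlier catalogue
#'
#' @param catalog result of [catalog_outlier_genes()].
#' @param test,variant,tier,flank selection keys.
#' @return character vector of symbols (possibly empty).
#' @export
tier_gene_set <- function(catalog, test, variant = "pooled", tier = 1e-3,
                          flank = 0) {
  sel <- catalog$test == test & catalog$variant == variant &
    catalog$tier == tier & catalog$flank == flank
  unique(catalog$symbol[sel])
}
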