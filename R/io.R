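#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal single-allele-pair VCF with `GT` genotypes and the stored
#' per-site `QUAL`. Missing genotypes are written as `./.`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"), ncol(gm$geno) > 0)
  v <- gm$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_codes[gm$geno[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt,
                format(v$qual, trim = TRUE), ".", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Uses vcfR for parsing. Multiallelic records are dropped with a message;
#' genotypes are converted to alt-allele dosages (phased or unphased).
#'
#' @param path VCF file (.vcf or .vcf.gz).
#' @param populations either a named character vector (sample -> population)
#'   or the path to a two-column TSV (`sample_id`, `population`). Samples
#'   absent from the mapping are dropped.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, populations) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  if (!all(biallelic)) {
    message(sum(!biallelic), " multiallelic records dropped")
    fix <- fix[biallelic, , drop = FALSE]
    gt_raw <- gt_raw[biallelic, , drop = FALSE]
  }
  dos <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  clean <- gsub("\\|", "/", gt_raw)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  dos <- t(dos)  # samples x variants
  rownames(dos) <- colnames(gt_raw)

  if (is.character(populations) && length(populations) == 1L &&
      file.exists(populations))
    populations <- read_populations(populations)
  keep <- rownames(dos) %in% names(populations)
  if (!all(keep))
    message(sum(!keep), " samples without a population label dropped")
  dos <- dos[keep, , drop = FALSE]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         qual = suppressWarnings(as.numeric(fix$QUAL)))
  geno_matrix(dos, variants, populations[rownames(dos)])
}

#' Read a sample-to-population mapping
#'
#' @param path TSV with columns `sample_id` and `population` (header required).
#' @return Named character vector, sample id -> population.
#' @export
read_populations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(df)))
  stats::setNames(df$population, df$sample_id)
}

#' Write a sample-to-population mapping
#' @param gm a [geno_matrix()].
#' @param path output TSV path.
#' @export
write_populations <- function(gm, path) {
  utils::write.table(data.frame(sample_id = gm$samples,
                                population = gm$populations),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the environment table
#'
#' Location x covariate table as TSV. Columns: `location`, `latitude`,
#' `longitude`, then `altitude` and `BIO1`..`BIO19`.
#' @param env data.frame as produced by [simulate_dataset()].
#' @param path file path.
#' @return `write_env` returns `path` invisibly; `read_env` the data.frame.
#' @export
write_env <- function(env, path) {
  stopifnot(nrow(env) > 0, all(covariate_names() %in% names(env)))
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env
#' @export
read_env <- function(path) {
  env <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(covariate_names(), names(env))
  if (length(missing))
    stop("environment table lacks covariates: ", paste(missing, collapse = ", "))
  env
}

#' Read a gene annotation (BED or GFF3) into a gene interval table
#'
#' BED input is taken as 0-based half-open with the symbol in the name
#' column; GFF3 `gene` records are converted from 1-based inclusive to the
#' same internal convention. Parsing is delegated to rtracklayer.
#'
#' @param path `.bed`, `.gff`, `.gff3` (optionally gzipped) annotation file.
#' @return data.frame (chrom, start, end, strand, symbol) with 0-based
#'   half-open coordinates.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  sym <- if (!is.null(gr$Name)) as.character(gr$Name)
         else if (!is.null(gr$name)) as.character(gr$name)
         else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
         else paste0("gene", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             symbol = sym)
}

#' Write gene intervals as BED
#'
#' @param genes data.frame (chrom, start, end, strand, symbol), 0-based
#'   half-open.
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  stopifnot(nrow(genes) > 0, all(genes$start < genes$end))
  utils::write.table(
    data.frame(genes$chrom,
               format(genes$start, scientific = FALSE, trim = TRUE),
               format(genes$end, scientific = FALSE, trim = TRUE),
               genes$symbol, 0L, genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write planted-truth loci as TSV
#' @param truth truth component of [simulate_dataset()] output.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  env <- truth$env_loci
  br <- truth$branch_loci
  rows <- rbind(
    if (nrow(env)) data.frame(chrom = env$chrom, pos = env$pos,
                              class = "env", param = paste0(env$covariate,
                                                            ":", env$beta)),
    if (nrow(br)) data.frame(chrom = br$chrom, pos = br$pos,
                             class = "branch", param = br$shifted_pops))
  if (is.null(rows))
    rows <- data.frame(chrom = character(), pos = integer(),
                       class = character(), param = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate gene list (one symbol per line)
#'
#' Symbols are trimmed and upper-cased; matching throughout the enrichment
#' module is case-insensitive.
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of unique upper-case symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}
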