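#' QC thresholds
#'
#' Defaults mirror a conventional short-read resequencing QC chain: site
#' quality (phred) >= 40, overall call rate >= 0.8, exact Hardy-Weinberg
#' p >= 1e-8, minor allele frequency >= 0.05, per-population call rate >=
#' 0.8, LD pruning in 500 kb windows advanced one variant at a time at
#' r^2 <= 0.8 (0.5 for the stringent comparison set), and KING-robust
#' kinship cutoffs 0.177 (first degree) / 0.0884 (second degree).
#'
#' @param min_qual minimum VCF QUAL retained.
#' @param max_missing minimum fraction of samples with a called genotype.
#' @param hwe_p_min exact Hardy-Weinberg p-value floor (pooled samples).
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param per_pop_call_rate minimum call rate required within every population.
#' @param ld_window_bp physical LD-pruning window in bp.
#' @param ld_step window advance in variants.
#' @param ld_r2 squared-correlation threshold above which the later marker of
#'   a pair is pruned.
#' @param kinship_first_degree,kinship_second_degree KING-robust kinship
#'   cutoffs for first/second-degree relatives.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_qual = 40, max_missing = 0.8, hwe_p_min = 1e-8,
                          maf_min = 0.05, per_pop_call_rate = 0.8,
                          ld_window_bp = 500000L, ld_step = 1L, ld_r2 = 0.8,
                          kinship_first_degree = 0.177,
                          kinship_second_degree = 0.0884) {
  th <- list(min_qual = min_qual, max_missing = max_missing,
             hwe_p_min = hwe_p_min, maf_min = maf_min,
             per_pop_call_rate = per_pop_call_rate,
             ld_window_bp = as.integer(ld_window_bp),
             ld_step = as.integer(ld_step), ld_r2 = ld_r2,
             kinship_first_degree = kinship_first_degree,
             kinship_second_degree = kinship_second_degree)
  fr <- c("max_missing", "maf_min", "per_pop_call_rate")
  stopifnot(all(unlist(th[fr]) >= 0), all(unlist(th[fr]) <= 1),
            min_qual > 0, hwe_p_min > 0, ld_window_bp > 0, ld_step > 0,
            ld_r2 > 0)
  structure(th, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditional on the observed allele counts, every
#' heterozygote count with the right parity is enumerated, its exact
#' probability computed, and the probabilities no larger than that of the
#' observed configuration are summed. Vectorized over sites.
#'
#' @param n_homref,n_het,n_homalt genotype-class counts (vectors of equal
#'   length).
#' @return p-values in (0, 1]; monomorphic sites return 1.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(length(n_homref) == length(n_het),
            length(n_het) == length(n_homalt),
            all(n_homref >= 0), all(n_het >= 0), all(n_homalt >= 0),
            all(n_homref + n_het + n_homalt >= 1))
  mapply(function(n0, n1, n2) {
    N <- n0 + n1 + n2
    na <- 2L * n0 + n1           # allele "a" count (as labelled; symmetric)
    nb <- 2L * n2 + n1
    if (na == 0L || nb == 0L) return(1.0)
    rare <- min(na, nb)
    hets <- seq(rare %% 2L, rare, by = 2L)
    # log P(het = h | allele counts): multinomial over genotype configurations
    logp <- lfactorial(na) + lfactorial(nb) + lfactorial(N) -
      lfactorial(na + nb) + hets * log(2) -
      lfactorial((na - hets) / 2) - lfactorial(hets) -
      lfactorial((nb - hets) / 2)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    obs <- p[match(n1, hets)]
    min(1, sum(p[p <= obs * (1 + 1e-9)]))
  }, n_homref, n_het, n_homalt, USE.NAMES = FALSE)
}

geno_class_counts <- function(g) {
  list(n0 = colSums(g == 0L, na.rm = TRUE),
       n1 = colSums(g == 1L, na.rm = TRUE),
       n2 = colSums(g == 2L, na.rm = TRUE))
}

#' Marker quality-control filters
#'
#' Applies, in order: site QUAL, overall call rate, biallelic-SNP check,
#' exact Hardy-Weinberg test over all samples pooled, minor allele frequency,
#' per-population call rate (every population must pass), and removal of
#' sites monomorphic across all study populations. Boundary values pass
#' (thresholds are inclusive).
#'
#' @param gm a [geno_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param autosomes_only drop records on X/Y/MT-style chromosome names first.
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (data.frame stage/removed/remaining; removals are additive).
#' @export
filter_markers <- function(gm, thresholds = qc_thresholds(),
                           autosomes_only = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(thresholds, "qc_thresholds"))
  stages <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(stage, keep) {
    stages <<- c(stages, stage)
    removed <<- c(removed, sum(!keep))
    gm <<- subset_geno(gm, variants = keep)
    remaining <<- c(remaining, ncol(gm$geno))
  }

  if (autosomes_only) {
    sex <- grepl("^(chr)?(X|Y|MT?|W|Z)$", gm$variants$chrom, ignore.case = TRUE)
    if (any(sex)) message(sum(sex), " non-autosomal records dropped")
    note("autosomes", !sex)
  }
  note("qual", !is.na(gm$variants$qual) & gm$variants$qual >= thresholds$min_qual)
  call_rate <- colMeans(!is.na(gm$geno))
  note("call_rate", call_rate >= thresholds$max_missing)
  note("biallelic_snp", nchar(gm$variants$ref) == 1L &
         nchar(gm$variants$alt) == 1L & gm$variants$alt != ".")

  cc <- geno_class_counts(gm$geno)
  hwe_p <- hwe_exact_test(cc$n0, cc$n1, cc$n2)
  note("hwe", hwe_p >= thresholds$hwe_p_min)

  cc <- geno_class_counts(gm$geno)
  an <- 2 * (cc$n0 + cc$n1 + cc$n2)
  af <- ifelse(an > 0, (cc$n1 + 2 * cc$n2) / an, NA_real_)
  maf <- pmin(af, 1 - af)
  note("maf", !is.na(maf) & maf >= thresholds$maf_min)

  pops <- unique(gm$populations)
  ok <- rep(TRUE, ncol(gm$geno))
  for (p in pops) {
    rows <- gm$populations == p
    ok <- ok & colMeans(!is.na(gm$geno[rows, , drop = FALSE])) >=
      thresholds$per_pop_call_rate
  }
  note("per_pop_call_rate", ok)

  cc <- geno_class_counts(gm$geno)
  ac <- cc$n1 + 2 * cc$n2
  an <- 2 * (cc$n0 + cc$n1 + cc$n2)
  note("monomorphic", ac > 0 & ac < an)

  if (ncol(gm$geno) == 0L)
    stop("all markers removed by QC filters")
  list(genotypes = gm,
       report = data.frame(stage = stages, removed = removed,
                           remaining = remaining))
}

#' Greedy LD pruning of a marker panel
#'
#' For each retained marker scanned left to right within a chromosome, the
#' squared Pearson correlation of genotype dosages (missing values
#' pairwise-deleted) is computed against every later marker within
#' `window_bp`; the later marker is pruned when r^2 exceeds `r2_max`.
#' Zero-variance markers have undefined r^2 and are never pruned here.
#' Markers on different chromosomes are never compared.
#'
#' @param gm a [geno_matrix()] with variants sorted by (chrom, pos).
#' @param window_bp physical window in bp.
#' @param step anchor advance in variants.
#' @param r2_max squared-correlation threshold (a pair strictly above it
#'   triggers pruning).
#' @return integer vector of retained variant indices (into `gm$variants`).
#' @export
ld_prune <- function(gm, window_bp = 500000L, step = 1L, r2_max = 0.8) {
  stopifnot(inherits(gm, "geno_matrix"))
  v <- gm$variants
  if (is.unsorted(order(v$chrom, v$pos))) stop("variants must be sorted")
  keep <- logical(ncol(gm$geno))
  for (cc in unique(v$chrom)) {
    idx <- which(v$chrom == cc)
    g <- gm$geno[, idx, drop = FALSE]
    storage.mode(g) <- "double"
    keep[idx] <- ld_prune_chrom(g, v$pos[idx], as.double(window_bp),
                                as.integer(step), as.double(r2_max))
  }
  which(keep)
}

#' KING-robust pairwise kinship
#'
#' For samples i and j over their jointly called SNPs:
#' `phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`, where `N_AaAa` counts
#' sites heterozygous in both, `N_AAaa` opposite homozygotes, and `N_Aa(.)`
#' heterozygous sites per sample. Robust to population structure; expected
#' values: 0.5 duplicates, 0.25 first-degree, 0.125 second-degree, <= 0
#' between populations.
#'
#' @param gm a [geno_matrix()] with >= 2 samples.
#' @return data.frame (`id1`, `id2`, `kinship`) over all unordered pairs;
#'   pairs where neither sample has a heterozygous call are `NA` (with a
#'   warning).
#' @export
king_kinship <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(gm$geno) >= 2)
  G <- t(gm$geno)                       # variants x samples
  na <- is.na(G)
  H <- (!na & G == 1L); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  A0 <- (!na & G == 0L); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A2 <- (!na & G == 2L); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  C <- 1 - na; storage.mode(C) <- "double"
  n_hethet <- crossprod(H)              # het in both
  n_opp <- crossprod(A0, A2) + crossprod(A2, A0)
  n_het_i <- crossprod(H, C)            # het in i, called in j
  denom <- n_het_i + t(n_het_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  pr <- which(upper.tri(phi), arr.ind = TRUE)
  out <- data.frame(id1 = gm$samples[pr[, 1]], id2 = gm$samples[pr[, 2]],
                    kinship = phi[pr])
  und <- denom[pr] == 0
  if (any(und)) {
    warning(sum(und), " pair(s) without heterozygous sites: kinship undefined")
    out$kinship[und] <- NA_real_
  }
  out
}

#' Remove samples until no close relatives remain
#'
#' Greedy removal: while any pair exceeds the kinship threshold, drop the
#' sample involved in the most above-threshold pairs (ties broken by
#' lexicographically smallest sample id). The remaining set is guaranteed to
#' contain no pair above the threshold.
#'
#' @param kinship data.frame from [king_kinship()].
#' @param threshold kinship above which a pair is "related"; default is the
#'   second-degree cutoff so first- and second-degree relatives are removed.
#' @return character vector of sample ids to remove (possibly empty).
#' @export
drop_relatives <- function(kinship, threshold = 0.0884) {
  rel <- kinship[!is.na(kinship$kinship) & kinship$kinship > threshold,
                 c("id1", "id2")]
  removed <- character(0)
  while (nrow(rel) > 0) {
    deg <- sort(table(c(rel$id1, rel$id2)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    rel <- rel[rel$id1 != victim & rel$id2 != victim, , drop = FALSE]
  }
  removed
}

#' Per-site nucleotide diversity within a population
#'
#' `pi = x (n - x) / choose(n, 2)` with `x` the alt-allele count and `n` the
#' called chromosomes; the fraction of discordant chromosome pairs. Sites
#' with fewer than two called chromosomes are skipped (`NA`).
#'
#' @param gm a [geno_matrix()].
#' @param population population label to restrict to (default: all samples).
#' @return list with `per_site` (vector, length = variants) and `mean`
#'   (average over defined sites).
#' @export
site_diversity <- function(gm, population = NULL) {
  g <- gm$geno
  if (!is.null(population)) {
    rows <- gm$populations == population
    if (!any(rows)) stop("unknown population: ", population)
    g <- g[rows, , drop = FALSE]
  }
  n <- 2 * colSums(!is.na(g))
  x <- colSums(g, na.rm = TRUE)
  pi <- ifelse(n >= 2, x * (n - x) / (n * (n - 1) / 2), NA_real_)
  list(per_site = pi, mean = mean(pi, na.rm = TRUE))
}
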