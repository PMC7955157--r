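#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks it against the known schema and
#' collects *all* problems into one error message (unknown keys are
#' rejected to guard against silent typos).
#'
#' Recognized keys: `vcf`, `populations`, `env`, `annotation` (paths),
#' `candidates` (named map of candidate-list paths), `out_dir`; `qc` (any
#' [qc_thresholds()] field); `pbs` (`focal`, `sister`, `outgroup`:
#' population label vectors); `envassoc` (`n_runs`, `seed`,
#' `omega_subsample`, `prior_beta`, `threshold_db`, `prune_r2`,
#' `covariates`); `tiers` (ascending, each < 0.01); `flanks`;
#' `universe_size`.
#'
#' @param path YAML file.
#' @return list of class `run_config`, or an error listing every problem.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  err <- function(...) errs <<- c(errs, paste0(...))

  known <- c("vcf", "populations", "env", "annotation", "candidates",
             "out_dir", "qc", "pbs", "envassoc", "tiers", "flanks",
             "universe_size")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) err("unknown key(s): ", paste(extra, collapse = ", "))

  for (p in c("vcf", "populations", "env", "annotation")) {
    if (is.null(cfg[[p]])) err("missing required path: ", p)
    else if (!file.exists(cfg[[p]])) err(p, " does not exist: ", cfg[[p]])
  }
  for (cl in names(cfg$candidates))
    if (!file.exists(cfg$candidates[[cl]]))
      err("candidate list '", cl, "' does not exist: ", cfg$candidates[[cl]])
  if (is.null(cfg$out_dir)) err("missing required path: out_dir")

  if (!is.null(cfg$qc)) {
    bad <- setdiff(names(cfg$qc), names(formals(qc_thresholds)))
    if (length(bad)) err("unknown qc key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$pbs)) {
    err("missing pbs group definitions (focal, sister, outgroup)")
  } else {
    for (g in c("focal", "sister", "outgroup"))
      if (is.null(cfg$pbs[[g]])) err("pbs: missing group '", g, "'")
    if (!is.null(cfg$pbs$outgroup) && length(cfg$pbs$outgroup) != 1)
      err("pbs: exactly one outgroup population must be defined")
  }
  cfg$tiers <- if (is.null(cfg$tiers)) c(1e-5, 1e-4, 1e-3) else
    sort(as.numeric(cfg$tiers))
  if (any(cfg$tiers >= 0.01)) err("tiers must all be < 0.01")
  cfg$flanks <- if (is.null(cfg$flanks)) c(0L, 100000L) else
    as.integer(cfg$flanks)
  cfg$universe_size <- if (is.null(cfg$universe_size)) 13510L else
    as.integer(cfg$universe_size)
  ea_known <- c("n_runs", "seed", "omega_subsample", "prior_beta",
                "threshold_db", "prune_r2", "covariates")
  bad <- setdiff(names(cfg$envassoc), ea_known)
  if (length(bad)) err("unknown envassoc key(s): ", paste(bad, collapse = ", "))
  ea <- cfg$envassoc
  cfg$envassoc <- list(
    n_runs = if (is.null(ea$n_runs)) 100L else as.integer(ea$n_runs),
    seed = if (is.null(ea$seed)) 1L else as.integer(ea$seed),
    omega_subsample = if (is.null(ea$omega_subsample)) 50000L else
      as.integer(ea$omega_subsample),
    prior_beta = if (is.null(ea$prior_beta)) c(-0.3, 0.3) else
      as.numeric(ea$prior_beta),
    threshold_db = if (is.null(ea$threshold_db)) 10 else
      as.numeric(ea$threshold_db),
    prune_r2 = if (is.null(ea$prune_r2)) 0.5 else as.numeric(ea$prune_r2),
    covariates = if (is.null(ea$covariates)) covariate_names() else
      as.character(ea$covariates))

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full landscape-genomics pipeline
#'
#' Executes, in order: QC (marker filters, relatedness removal, LD prune),
#' PBS scan with 9-SNP windows, the replicated environmental-association
#' protocol with covariate ranking, outlier-gene cataloguing, candidate
#' gene-set enrichment, and PCA summaries. Stage outputs are written as TSV
#' under `out_dir`; a YAML manifest records seeds, per-stage marker/sample
#' counts and output files. A stage whose output files already exist is
#' skipped unless `force = TRUE`.
#'
#' @param config a [validate_config()] result or path to a YAML config.
#' @param force recompute stages whose outputs already exist.
#' @return the manifest (invisibly), as written to
#'   `file.path(out_dir, "manifest.yaml")`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out, f)
  manifest <- list(config = unclass(config), stages = list())
  done <- function(f) !force && all(file.exists(pth(f)))
  wtsv <- function(df, f)
    utils::write.table(df, pth(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  th <- do.call(qc_thresholds, if (is.null(config$qc)) list() else config$qc)

  ## qc --------------------------------------------------------------------
  qc_files <- c("qc_filtered.vcf", "qc_report.tsv", "qc_samples_kept.tsv")
  if (done(qc_files)) {
    stage_log("qc", "outputs exist, skipping (use force = TRUE to redo)")
    gm <- read_vcf(pth("qc_filtered.vcf"), read_populations(pth("qc_samples_kept.tsv")))
  } else {
    gm <- read_vcf(config$vcf, config$populations)
    stage_log("qc", nrow(gm$geno), " samples x ", ncol(gm$geno), " markers in")
    fl <- filter_markers(gm, th)
    gm <- fl$genotypes
    kin <- king_kinship(gm)
    rm_samples <- drop_relatives(kin, th$kinship_second_degree)
    if (length(rm_samples)) {
      stage_log("qc", length(rm_samples), " related sample(s) removed: ",
                paste(rm_samples, collapse = ", "))
      gm <- subset_geno(gm, samples = setdiff(gm$samples, rm_samples))
      gm <- filter_markers(gm, th)$genotypes  # re-check per-pop filters
    }
    write_vcf(gm, pth("qc_filtered.vcf"))
    wtsv(fl$report, "qc_report.tsv")
    write_populations(gm, pth("qc_samples_kept.tsv"))
    stage_log("qc", nrow(gm$geno), " samples x ", ncol(gm$geno),
              " markers retained")
  }
  manifest$stages$qc <- list(samples = nrow(gm$geno),
                             markers = ncol(gm$geno), files = qc_files)

  ## pbs -------------------------------------------------------------------
  if (done("pbs_scan.tsv") && done("fst_pairwise.tsv")) {
    stage_log("pbs", "outputs exist, skipping")
    scan_pbs <- utils::read.delim(pth("pbs_scan.tsv"))
  } else {
    scan_pbs <- pbs_scan(gm, config$pbs$focal, config$pbs$sister,
                         config$pbs$outgroup)
    wtsv(scan_pbs, "pbs_scan.tsv")
    wtsv(pairwise_fst_matrix(gm), "fst_pairwise.tsv")
    stage_log("pbs", sum(!is.na(scan_pbs$pbs_raw)), " markers with PBS; ",
              sum(!is.na(scan_pbs$pbs_mean)), " with full windows")
  }
  manifest$stages$pbs <- list(markers_raw = sum(!is.na(scan_pbs$pbs_raw)),
                              markers_windowed = sum(!is.na(scan_pbs$pbs_mean)),
                              files = c("pbs_scan.tsv", "fst_pairwise.tsv"))

  ## envassoc --------------------------------------------------------------
  ea <- config$envassoc
  if (done("bf_scan.tsv") && done("covariate_ranking.tsv")) {
    stage_log("envassoc", "outputs exist, skipping")
    bf_tab <- utils::read.delim(pth("bf_scan.tsv"))
    ranking <- utils::read.delim(pth("covariate_ranking.tsv"))
  } else {
    env <- read_env(config$env)
    pruned <- ld_prune(gm, th$ld_window_bp, th$ld_step, ea$prune_r2)
    stage_log("envassoc", length(pruned), " markers in the r2<=",
              ea$prune_r2, " pruned comparison set")
    scan <- run_env_protocol(gm, env, covariates = ea$covariates,
                             n_runs = ea$n_runs, seed = ea$seed,
                             omega_subsample = ea$omega_subsample,
                             prior_beta = ea$prior_beta,
                             pruned_idx = pruned,
                             threshold_db = ea$threshold_db)
    bf_tab <- scan$bf
    ranking <- rank_covariates(scan)
    wtsv(bf_tab, "bf_scan.tsv")
    wtsv(ranking, "covariate_ranking.tsv")
    stage_log("envassoc", "top covariate: ", ranking$covariate[1],
              " (mean count ", round(ranking$mean_count[1], 1), ")")
  }
  manifest$stages$envassoc <- list(n_runs = ea$n_runs, seed = ea$seed,
                                   top_covariate = ranking$covariate[1],
                                   files = c("bf_scan.tsv",
                                             "covariate_ranking.tsv"))

  ## outliers --------------------------------------------------------------
  genes <- read_annotation(config$annotation)
  scan_all <- merge(scan_pbs[c("chrom", "pos", "pbs_raw", "pbs_mean",
                               "pbs_median")],
                    bf_tab, by = c("chrom", "pos"), all = TRUE)
  scan_all <- scan_all[order(scan_all$chrom, scan_all$pos), ]
  catalog <- catalog_outlier_genes(scan_all, genes, tiers = config$tiers,
                                   flanks = config$flanks)
  wtsv(catalog, "outlier_genes.tsv")
  manifest$stages$outliers <- list(n_rows = nrow(catalog),
                                   files = "outlier_genes.tsv")

  ## enrichment ------------------------------------------------------------
  if (length(config$candidates)) {
    cands <- lapply(config$candidates, read_gene_list)
    tests <- intersect(c("pbs", "altitude"),
                       unique(catalog$test))
    rep_df <- overlap_report(catalog, cands, tests = tests,
                             tiers = config$tiers[config$tiers >= 1e-4],
                             universe_size = config$universe_size)
    wtsv(rep_df, "enrichment.tsv")
    manifest$stages$enrichment <- list(n_tests = nrow(rep_df),
                                       files = "enrichment.tsv")
  }

  ## pca -------------------------------------------------------------------
  env <- read_env(config$env)
  pe <- env_pca(env)
  wtsv(data.frame(component = seq_along(pe$variance_explained),
                  variance_explained = pe$variance_explained),
       "env_pca_variance.tsv")
  wtsv(data.frame(location = rownames(pe$scores), pe$scores),
       "env_pca_scores.tsv")
  pg <- genotype_pca(gm, n_components = 10)
  wtsv(data.frame(sample = rownames(pg$scores),
                  population = gm$populations, pg$scores),
       "genotype_pca_scores.tsv")
  manifest$stages$pca <- list(
    env_pc1 = round(pe$variance_explained[1], 4),
    files = c("env_pca_variance.tsv", "env_pca_scores.tsv",
              "genotype_pca_scores.tsv"))

  yaml::write_yaml(manifest, pth("manifest.yaml"))
  invisible(manifest)
}
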