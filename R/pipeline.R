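# Staged pipeline driver: each stage reads the previous stage's plain-text
# artifacts from the output directory and writes its own, so any stage can be
# rerun in isolation and a full run is reproducible from the config alone.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its conventional default:
#' significance threshold 0.05 (BH-adjusted), beta-state boundary 0.5,
#' missingness filter 0.8, 20 top genes, 10,000 heatmap CpGs, 20 top
#' enrichment terms, enrichment cutoffs 0.05 / 0.2.
#'
#' @param out_dir Directory for stage artifacts.
#' @param alpha Adjusted-p significance threshold.
#' @param beta_cutoff State boundary for directionality.
#' @param max_missing_fraction Probe missingness filter.
#' @param n_top_genes Genes per crossing direction.
#' @param n_heatmap_cpgs Significant CpGs sampled for visualisation.
#' @param n_top_terms Enrichment terms reported.
#' @param pvalue_cutoff,qvalue_cutoff Enrichment reporting filters.
#' @param seed Global seed; stages derive independent sub-seeds from it.
#' @param simulation A [sim_config()] for the simulate stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "methcross_out", alpha = 0.05,
                            beta_cutoff = 0.5, max_missing_fraction = 0.8,
                            n_top_genes = 20L, n_heatmap_cpgs = 10000L,
                            n_top_terms = 20L, pvalue_cutoff = 0.05,
                            qvalue_cutoff = 0.2, seed = 1L,
                            simulation = sim_config(seed = seed)) {
  cfg <- list(out_dir = out_dir, alpha = alpha, beta_cutoff = beta_cutoff,
              max_missing_fraction = max_missing_fraction,
              n_top_genes = as.integer(n_top_genes),
              n_heatmap_cpgs = as.integer(n_heatmap_cpgs),
              n_top_terms = as.integer(n_top_terms),
              pvalue_cutoff = pvalue_cutoff, qvalue_cutoff = qvalue_cutoff,
              seed = as.integer(seed), simulation = simulation)
  for (f in c("alpha", "beta_cutoff", "max_missing_fraction",
              "pvalue_cutoff", "qvalue_cutoff"))
    if (!is_fraction(cfg[[f]])) stopf("invalid config field: %s must be in [0, 1]", f)
  for (f in c("n_top_genes", "n_heatmap_cpgs", "n_top_terms"))
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) stopf("invalid config field: %s must be a positive count", f)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML (or JSON-compatible) file whose top-level keys mirror the
#' [pipeline_config()] arguments, with an optional nested `simulation` block
#' for [sim_config()]. Explicit `overrides` (e.g. from a command line) take
#' precedence over file values, which take precedence over defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of overriding fields.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else list()
  vals[names(overrides)] <- overrides
  sim_args <- vals$simulation
  vals$simulation <- NULL
  bad <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) stopf("unknown simulation field(s): %s", paste(bad, collapse = ", "))
    if (!is.null(sim_args$island_proportions))
      sim_args$island_proportions <- unlist(sim_args$island_proportions)
    if (is.null(sim_args$seed) && !is.null(vals$seed)) sim_args$seed <- vals$seed
    vals$simulation <- do.call(sim_config, sim_args)
  } else if (!is.null(vals$seed)) {
    vals$simulation <- sim_config(seed = vals$seed)
  }
  do.call(pipeline_config, vals)
}

art <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- art(cfg, name)
  if (!file.exists(p))
    stopf("missing input %s: run the '%s' stage first", p, producer)
  p
}

log_count <- function(stage, fmt, ...) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic datasets, manifest, gene sets, ground
#' truth), `preprocess` (merge + missingness filter + M transform), `dmp`
#' (moderated differential methylation), `direction` (threshold-crossing
#' classification and top-gene ranking), `crosstab` (stratified
#' cross-tabulation), `enrich` (over-representation analysis), `viz`
#' (volcano, heatmap, dendrogram, PCA), or `all` to chain everything. Each
#' stage reads its predecessors' TSV artifacts from `config$out_dir` and
#' writes its own; a run manifest records the configuration, seed, package
#' version and per-stage row counts.
#'
#' @param stage Stage name (see above).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config()) {
  stages <- c("simulate", "preprocess", "dmp", "direction", "crosstab", "enrich", "viz")
  stage <- match.arg(stage, c(stages, "all"))
  if (stage == "all") {
    out <- unlist(lapply(stages, run_pipeline, config = config))
    return(invisible(out))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- switch(stage,
    simulate = stage_simulate(config),
    preprocess = stage_preprocess(config),
    dmp = stage_dmp(config),
    direction = stage_direction(config),
    crosstab = stage_crosstab(config),
    enrich = stage_enrich(config),
    viz = stage_viz(config))
  update_run_manifest(config, stage, written)
  invisible(written)
}

stage_simulate <- function(cfg) {
  sim_cfg <- cfg$simulation
  manifest <- generate_manifest(sim_cfg)
  sim <- generate_beta(manifest, sim_cfg)
  db <- generate_gmt(manifest, sim_cfg, truth = sim$truth)
  paths <- c(manifest = art(cfg, "manifest.tsv"),
             gmt = art(cfg, "gene_sets.gmt"),
             truth = art(cfg, "truth.tsv"))
  write_manifest_tsv(manifest, paths[["manifest"]])
  write_gmt(db, paths[["gmt"]])
  write_truth_tsv(sim$truth, paths[["truth"]])
  # one matrix + sheet per dataset block, so preprocess exercises the merge
  for (ds in unique(sim$sheet$dataset_id)) {
    cols <- sim$sheet$sample_id[sim$sheet$dataset_id == ds]
    bp <- art(cfg, sprintf("beta_%s.tsv", ds))
    sp <- art(cfg, sprintf("samples_%s.csv", ds))
    write_beta_tsv(sim$beta[, cols, drop = FALSE], bp)
    write_sample_sheet(sim$sheet[sim$sheet$dataset_id == ds, ], sp)
    paths[[sprintf("beta_%s", ds)]] <- bp
    paths[[sprintf("samples_%s", ds)]] <- sp
  }
  log_count("simulate", "%d probes x %d samples in %d dataset(s)",
            nrow(sim$beta), ncol(sim$beta), length(unique(sim$sheet$dataset_id)))
  paths
}

stage_preprocess <- function(cfg) {
  beta_files <- sort(list.files(cfg$out_dir, "^beta_DS.*\\.tsv$", full.names = TRUE))
  if (!length(beta_files))
    stopf("no per-dataset beta matrices in %s: run the 'simulate' stage first (or place beta_DS*.tsv / samples_DS*.csv there)",
          cfg$out_dir)
  sheet_files <- sub("beta_(DS[^.]*)\\.tsv$", "samples_\\1.csv", beta_files)
  missing <- !file.exists(sheet_files)
  if (any(missing)) stopf("missing sample sheet(s): %s", paste(sheet_files[missing], collapse = ", "))
  merged <- merge_datasets(lapply(beta_files, read_beta_tsv),
                           lapply(sheet_files, read_sample_sheet))
  filtered <- filter_missing(merged$beta, cfg$max_missing_fraction)
  log_count("preprocess", "merged %d dataset(s); %d probes retained (%d removed by > %.0f%% missingness)",
            length(beta_files), nrow(filtered), attr(filtered, "n_removed"),
            100 * cfg$max_missing_fraction)
  m <- beta_to_m(filtered)
  paths <- c(beta = art(cfg, "beta_merged.tsv"),
             sheet = art(cfg, "samples.csv"),
             m = art(cfg, "mvalues.tsv"))
  write_beta_tsv(filtered, paths[["beta"]])
  write_sample_sheet(merged$sheet, paths[["sheet"]])
  write_beta_tsv(m, paths[["m"]])
  paths
}

stage_dmp <- function(cfg) {
  beta <- read_beta_tsv(require_artifact(cfg, "beta_merged.tsv", "preprocess"))
  sheet <- read_sample_sheet(require_artifact(cfg, "samples.csv", "preprocess"))
  fit <- dmp_fit(beta, sheet, alpha = cfg$alpha, max_missing_fraction = NULL)
  log_count("dmp", "%d probes tested, %d significant at adj.P < %.3g",
            nrow(fit$table), sum(fit$table$significant, na.rm = TRUE), cfg$alpha)
  paths <- c(dmp = art(cfg, "dmp_table.tsv"), dmp_full = art(cfg, "dmp_full.tsv"))
  write_dmp_tsv(fit, paths[["dmp"]])
  utils::write.table(fit$table, paths[["dmp_full"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

read_dmp_full <- function(cfg) {
  utils::read.table(require_artifact(cfg, "dmp_full.tsv", "dmp"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(probe_id = "character"))
}

stage_direction <- function(cfg) {
  tab <- read_dmp_full(cfg)
  manifest <- read_manifest_tsv(require_artifact(cfg, "manifest.tsv", "simulate"))
  directions <- classify_direction(tab, cutoff = cfg$beta_cutoff)
  top <- rank_top_genes(tab, directions, manifest, n_top = cfg$n_top_genes)
  sig_cross <- table(directions$change_class[tab$significant &
                       directions$change_class %in% c("low_to_high", "high_to_low")])
  log_count("direction", "significant crossings: %s",
            paste(names(sig_cross), sig_cross, sep = "=", collapse = ", "))
  paths <- c(directions = art(cfg, "directions.tsv"),
             top_genes = art(cfg, "top_genes.tsv"))
  utils::write.table(directions, paths[["directions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_top_genes_tsv(top, paths[["top_genes"]])
  paths
}

read_tsv_chr <- function(path, chr_cols) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = stats::setNames(rep("character", length(chr_cols)), chr_cols),
                    na.strings = "NA", quote = "", fill = TRUE)
}

stage_crosstab <- function(cfg) {
  tab <- read_dmp_full(cfg)
  manifest <- read_manifest_tsv(require_artifact(cfg, "manifest.tsv", "simulate"))
  directions <- read_tsv_chr(require_artifact(cfg, "directions.tsv", "direction"), "probe_id")
  top <- read_tsv_chr(require_artifact(cfg, "top_genes.tsv", "direction"),
                      c("gene_symbol", "cpg_ids", "refseq_ids"))
  ann <- attach_annotation(tab, manifest)
  ct <- crosstab(ann, directions, top)
  log_count("crosstab", "%d significant CpG-feature assignments tabulated",
            attr(ct, "total_assignments"))
  path <- c(crosstab = art(cfg, "crosstab.tsv"))
  write_crosstab_tsv(ct, path)
  path
}

stage_enrich <- function(cfg) {
  tab <- read_dmp_full(cfg)
  manifest <- read_manifest_tsv(require_artifact(cfg, "manifest.tsv", "simulate"))
  db <- read_gmt(require_artifact(cfg, "gene_sets.gmt", "simulate"))
  top <- read_tsv_chr(require_artifact(cfg, "top_genes.tsv", "direction"),
                      c("gene_symbol", "cpg_ids", "refseq_ids"))
  universe <- unique(unlist(split_semicolon(manifest$UCSC_RefGene_Name)))
  sig_probes <- tab$probe_id[tab$significant %in% TRUE]
  query <- unique(unlist(split_semicolon(
    manifest$UCSC_RefGene_Name[manifest$IlmnID %in% sig_probes])))
  if (!length(query)) stopf("no genes annotated to significant probes")
  rec <- ora_test(query, db, universe, pvalue_cutoff = cfg$pvalue_cutoff,
                  qvalue_cutoff = cfg$qvalue_cutoff)
  rec <- intersect_top_genes(top_terms(rec, cfg$n_top_terms), top)
  log_count("enrich", "%d genes in query, %d enriched term(s) reported",
            length(query), nrow(rec))
  path <- c(enrichment = art(cfg, "enrichment.tsv"))
  write_enrichment_tsv(rec, path)
  path
}

stage_viz <- function(cfg) {
  tab <- read_dmp_full(cfg)
  beta <- read_beta_tsv(require_artifact(cfg, "beta_merged.tsv", "preprocess"))
  sheet <- read_sample_sheet(require_artifact(cfg, "samples.csv", "preprocess"))
  paths <- c(volcano = art(cfg, "volcano.png"),
             heatmap = art(cfg, "heatmap.png"),
             dendrogram = art(cfg, "dendrogram.png"),
             pca = art(cfg, "pca.png"),
             sampled = art(cfg, "sampled_probes.txt"),
             zscores = art(cfg, "zscores.tsv"),
             leaf_order = art(cfg, "leaf_order.txt"),
             pca_scores = art(cfg, "pca_scores.tsv"))
  volcano(tab, alpha = cfg$alpha, file = paths[["volcano"]])
  sig <- tab$probe_id[tab$significant %in% TRUE]
  if (length(sig) < 2L) stopf("fewer than 2 significant probes; nothing to visualise")
  sampled <- suppressWarnings(
    sample_significant(sig, cfg$n_heatmap_cpgs, seed = cfg$seed + 100L))
  z <- zscore_rows(beta[sampled, , drop = FALSE])
  log_count("viz", "%d significant probes, %d sampled, %d z-scored rows",
            length(sig), length(sampled), nrow(z))
  hc <- hierarchical_cluster(z, "columns")
  plot_heatmap(z, sheet, file = paths[["heatmap"]])
  plot_dendrogram(hc, sheet, file = paths[["dendrogram"]])
  pca <- pca_samples(z)
  plot_pca(pca, sheet, file = paths[["pca"]])
  writeLines(sampled, paths[["sampled"]])
  write_beta_tsv(z, paths[["zscores"]])
  writeLines(hc$labels[hc$order], paths[["leaf_order"]])
  utils::write.table(data.frame(sample_id = rownames(pca$scores),
                                pca$scores[, 1:min(5, ncol(pca$scores))],
                                check.names = FALSE),
                     paths[["pca_scores"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

update_run_manifest <- function(cfg, stage, written) {
  path <- art(cfg, "run_manifest.txt")
  counts <- vapply(written, function(p) {
    if (!file.exists(p)) return(NA_integer_)
    if (grepl("\\.(tsv|csv|txt|gmt)$", p)) length(readLines(p)) else NA_integer_
  }, integer(1))
  lines <- c(
    sprintf("[%s] stage=%s package=methcross %s seed=%d alpha=%g beta_cutoff=%g",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
            as.character(utils::packageVersion("methcross")),
            cfg$seed, cfg$alpha, cfg$beta_cutoff),
    sprintf("  %s: %s (%s lines)", names(written), written,
            ifelse(is.na(counts), "-", counts)),
    ""
  )
  cat(lines, file = path, sep = "\n", append = file.exists(path))
  invisible(path)
}
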