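# Synthetic 450K-style data: bimodal beta values, planted threshold-crossing
# effects, multi-dataset structure, probe-level missingness, many-to-many
# probe-gene annotation, and GMT gene sets with planted enrichment.

ISLAND_CATEGORIES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
REFGENE_GROUPS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic methylation study. Defaults mirror the
#' two-group gingival-tissue design the package targets: 34 control and 31
#' case samples spread over 3 array datasets, about 30\% of probes
#' differentially methylated, and CpG-island relation frequencies matching a
#' typical 450K significant-probe profile (Island 19.86\%, N_Shore 12.60\%,
#' S_Shore 9.80\%, N_Shelf 5.20\%, S_Shelf 4.77\%, OpenSea 47.77\%).
#'
#' @param n_probes Number of CpG probes.
#' @param n_control,n_case Samples per group (together at least 4).
#' @param n_datasets Number of dataset blocks the samples are partitioned into.
#' @param frac_dmp Fraction of probes with a planted group effect.
#' @param frac_crossing_low_high Fraction of probes planted to cross the
#'   beta = 0.5 boundary upward (control low, case high). Counted within
#'   `frac_dmp`.
#' @param frac_crossing_high_low As above, downward.
#' @param effect_size_m Planted group shift on the M (logit2) scale.
#' @param within_group_sd_m Within-group standard deviation on the M scale.
#' @param missing_rate Element-wise missingness rate for ordinary probes.
#' @param frac_high_missing_probes Fraction of probes engineered to exceed the
#'   80\% missingness filter.
#' @param island_proportions Named numeric vector over exactly
#'   `Island, N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea`, summing to 1.
#' @param batch_shift_m Optional per-dataset M-scale shift (default 0: dataset
#'   blocks carry no batch effect).
#' @param seed Integer seed; all generator functions are reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_control = 34L,
                       n_case = 31L,
                       n_datasets = 3L,
                       frac_dmp = 0.30,
                       frac_crossing_low_high = 0.05,
                       frac_crossing_high_low = 0.05,
                       effect_size_m = 2,
                       within_group_sd_m = 1,
                       missing_rate = 0.02,
                       frac_high_missing_probes = 0.01,
                       island_proportions = c(Island = 0.1986, N_Shore = 0.1260,
                                              S_Shore = 0.0980, N_Shelf = 0.0520,
                                              S_Shelf = 0.0477, OpenSea = 0.4777),
                       batch_shift_m = 0,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_control = as.integer(n_control),
              n_case = as.integer(n_case), n_datasets = as.integer(n_datasets),
              frac_dmp = frac_dmp,
              frac_crossing_low_high = frac_crossing_low_high,
              frac_crossing_high_low = frac_crossing_high_low,
              effect_size_m = effect_size_m,
              within_group_sd_m = within_group_sd_m,
              missing_rate = missing_rate,
              frac_high_missing_probes = frac_high_missing_probes,
              island_proportions = island_proportions,
              batch_shift_m = batch_shift_m,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_probes) || cfg$n_probes < 1L) stopf("n_probes must be >= 1")
  for (f in c("frac_dmp", "frac_crossing_low_high", "frac_crossing_high_low",
              "missing_rate", "frac_high_missing_probes"))
    if (!is_fraction(cfg[[f]])) stopf("%s must be a fraction in [0, 1]", f)
  if (cfg$frac_crossing_low_high + cfg$frac_crossing_high_low > cfg$frac_dmp + 1e-12)
    stopf("crossing fractions must not exceed frac_dmp")
  ip <- cfg$island_proportions
  if (!setequal(names(ip), ISLAND_CATEGORIES) || length(ip) != 6L)
    stopf("island_proportions must cover exactly: %s",
          paste(ISLAND_CATEGORIES, collapse = ", "))
  if (any(ip < 0) || abs(sum(ip) - 1) > 1e-6)
    stopf("island_proportions must be non-negative and sum to 1 (got %.6f)", sum(ip))
  if (cfg$n_datasets < 1L || cfg$n_datasets > cfg$n_control + cfg$n_case)
    stopf("n_datasets must be between 1 and the total sample count")
  if (cfg$within_group_sd_m <= 0) stopf("within_group_sd_m must be positive")
  cfg
}

# Split n items into k nearly equal consecutive blocks; returns block index.
block_assign <- function(n, k) rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))

#' Generate a synthetic probe annotation manifest
#'
#' Emulates the Illumina 450K manifest: per probe a CpG-island relation
#' category (drawn from `island_proportions`), zero or more gene symbols with
#' index-aligned gene-structure groups, and RefSeq ids mirroring the symbols.
#' Some probes map to several genes and most genes own several probes;
#' probes with no gene have blank annotation fields.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `IlmnID, CHR, MAPINFO, UCSC_RefGene_Name,
#'   UCSC_RefGene_Group, Relation_to_Island, RefSeq_ID` (multi-values
#'   semicolon-delimited).
#' @export
generate_manifest <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_probes
  with_seed(config$seed, {
    probe_id <- sprintf("cg%08d", seq_len(n))
    chr <- sample(c(1:22, "X"), n, replace = TRUE)
    pos <- sample.int(2e8L, n, replace = TRUE)
    relation <- sample(names(config$island_proportions), n, replace = TRUE,
                       prob = config$island_proportions)
    # many-to-many probe-gene structure: pool sized so genes average ~1.6
    # probes each (some own several, some none map at all)
    n_genes <- max(2L, round(n / 1.5))
    pool <- sprintf("G%06d", seq_len(n_genes))
    k_genes <- sample(0:3, n, replace = TRUE, prob = c(0.25, 0.50, 0.18, 0.07))
    gene_lists <- lapply(k_genes, function(k)
      if (k == 0L) character(0) else sample(pool, k))
    group_lists <- lapply(k_genes, function(k)
      if (k == 0L) character(0) else sample(REFGENE_GROUPS, k, replace = TRUE))
    refseq_lists <- lapply(gene_lists, function(g) sub("^G", "NM_", g))
    data.frame(
      IlmnID = probe_id,
      CHR = chr,
      MAPINFO = pos,
      UCSC_RefGene_Name = join_semicolon(gene_lists),
      UCSC_RefGene_Group = join_semicolon(group_lists),
      Relation_to_Island = relation,
      RefSeq_ID = join_semicolon(refseq_lists),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic beta matrix with planted effects
#'
#' Per-probe baseline means are drawn from a three-component mixture on the M
#' scale (low mode near beta 0.15, high mode near 0.85, and a mid component
#' near 0.5 so threshold crossings are attainable). Planted crossing probes
#' get a control-group mean strictly below beta 0.5 and a case mean at or
#' above it (or symmetrically downward), separated by `effect_size_m` on the
#' M scale; planted non-crossing effects shift away from the boundary. Sample
#' values are the group mean plus Gaussian noise on the M scale, mapped back
#' to beta. Missingness is injected element-wise at `missing_rate`, plus a set
#' of probes engineered to exceed the 80\% missingness filter.
#'
#' @param manifest Manifest from [generate_manifest()] (defines the probe set).
#' @param config A [sim_config()].
#' @return List with `beta` (matrix), `sheet` (sample sheet data frame) and
#'   `truth` (per-probe ground truth: `is_dmp`, `planted_class`,
#'   `true_mean_beta_control`, `true_mean_beta_case`, `high_missing`).
#' @export
generate_beta <- function(manifest, config) {
  config <- validate_sim_config(config)
  if (!nrow(manifest)) stopf("manifest is empty")
  n <- nrow(manifest)
  nc <- config$n_control; nk <- config$n_case
  if (nc + nk < 4L) stopf("need at least 4 samples for variance estimation")
  e <- config$effect_size_m

  with_seed(config$seed + 1L, {
    # plant probe roles
    n_lh <- round(config$frac_crossing_low_high * n)
    n_hl <- round(config$frac_crossing_high_low * n)
    n_dmp <- max(round(config$frac_dmp * n), n_lh + n_hl)
    role <- rep("stable", n)
    dmp_idx <- sample.int(n, n_dmp)
    role[dmp_idx] <- "noncross"
    if (n_lh) role[dmp_idx[seq_len(n_lh)]] <- "low_to_high"
    if (n_hl) role[dmp_idx[n_lh + seq_len(n_hl)]] <- "high_to_low"

    # baseline mixture on the M scale: modes at beta ~ 0.15 / 0.85 / 0.5
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.35, 0.20))
    mu0 <- c(log2(0.15 / 0.85), log2(0.85 / 0.15), 0)[comp] + stats::rnorm(n, 0, 0.8)

    mu_ctrl <- mu0
    mu_case <- mu0
    lh <- role == "low_to_high"
    hl <- role == "high_to_low"
    ncx <- role == "noncross"
    # crossing probes: control mean inside (-0.85e, -0.15e) so both the
    # control and case true means keep a clear margin from the 0.5 boundary
    mu_ctrl[lh] <- -stats::runif(sum(lh), 0.15 * e, 0.85 * e)
    mu_case[lh] <- mu_ctrl[lh] + e
    mu_ctrl[hl] <- stats::runif(sum(hl), 0.15 * e, 0.85 * e)
    mu_case[hl] <- mu_ctrl[hl] - e
    # non-crossing effects shift away from the boundary (state preserved)
    mu_case[ncx] <- mu_ctrl[ncx] + ifelse(mu_ctrl[ncx] >= 0, e, -e)

    # sample sheet: groups partitioned into nearly equal dataset blocks
    sample_id <- sprintf("S%03d", seq_len(nc + nk))
    group <- c(rep("Control", nc), rep("Periodontitis", nk))
    dataset_id <- sprintf("DS%d", c(block_assign(nc, config$n_datasets),
                                    block_assign(nk, config$n_datasets)))
    sheet <- data.frame(sample_id = sample_id, group = group,
                        dataset_id = dataset_id, stringsAsFactors = FALSE)

    mu <- cbind(matrix(mu_ctrl, n, nc), matrix(mu_case, n, nk))
    if (config$batch_shift_m != 0) {
      ds <- as.integer(factor(dataset_id, levels = unique(dataset_id)))
      mu <- mu + matrix(config$batch_shift_m * (ds - 1), n, nc + nk, byrow = TRUE)
    }
    m <- mu + stats::rnorm(n * (nc + nk), 0, config$within_group_sd_m)
    beta <- m_to_beta(m)
    dimnames(beta) <- list(manifest$IlmnID, sample_id)

    # element-wise missingness, then engineered high-missing probes
    ns <- nc + nk
    if (config$missing_rate > 0)
      beta[stats::runif(length(beta)) < config$missing_rate] <- NA_real_
    n_high <- round(config$frac_high_missing_probes * n)
    high_missing <- rep(FALSE, n)
    if (n_high > 0) {
      hi_idx <- sample(which(role == "stable"), min(n_high, sum(role == "stable")))
      high_missing[hi_idx] <- TRUE
      n_miss <- floor(0.8 * ns) + 1L  # strictly more than 80% missing
      for (i in hi_idx) beta[i, sample.int(ns, n_miss)] <- NA_real_
    }

    truth <- data.frame(
      probe_id = manifest$IlmnID,
      is_dmp = role != "stable",
      planted_class = ifelse(role %in% c("low_to_high", "high_to_low"), role, "stable"),
      true_mean_beta_control = m_to_beta(mu_ctrl),
      true_mean_beta_case = m_to_beta(mu_case),
      true_mean_m_control = mu_ctrl,
      true_mean_m_case = mu_case,
      high_missing = high_missing,
      stringsAsFactors = FALSE
    )
    list(beta = beta, sheet = sheet, truth = truth)
  })
}

#' Generate synthetic gene sets as a GMT collection
#'
#' Writes `n_terms` gene sets over the manifest's gene universe. The first
#' `enriched_terms` sets are seeded with genes annotated to planted
#' differentially methylated probes (at `enriched_fraction` of their members),
#' so over-representation is detectable downstream; remaining terms are drawn
#' uniformly from the universe.
#'
#' @param manifest Manifest from [generate_manifest()].
#' @param config A [sim_config()].
#' @param n_terms Total number of gene sets.
#' @param enriched_terms Number of sets seeded with planted genes (requires
#'   `truth` when positive).
#' @param truth Ground-truth table from [generate_beta()] (identifies planted
#'   probes).
#' @param term_size Integer range of set sizes, clipped to the universe.
#' @param enriched_fraction Fraction of an enriched term drawn from planted
#'   genes (default 0.8).
#' @param path Optional file path; when given the collection is also written
#'   as GMT.
#' @return A `gene_set_db` (invisibly also written to `path` if given).
#' @export
generate_gmt <- function(manifest, config, n_terms = 50L, enriched_terms = 5L,
                         truth = NULL, term_size = c(10L, 60L),
                         enriched_fraction = 0.8, path = NULL) {
  config <- validate_sim_config(config)
  if (n_terms < enriched_terms) stopf("n_terms must be >= enriched_terms")
  universe <- unique(unlist(split_semicolon(manifest$UCSC_RefGene_Name)))
  if (!length(universe)) stopf("manifest carries no genes")
  planted <- character(0)
  if (enriched_terms > 0L) {
    if (is.null(truth)) stopf("truth is required to seed enriched terms")
    dmp_probes <- truth$probe_id[truth$is_dmp]
    planted <- unique(unlist(split_semicolon(
      manifest$UCSC_RefGene_Name[manifest$IlmnID %in% dmp_probes])))
    if (!length(planted)) stopf("no planted genes available for enriched terms")
  }
  with_seed(config$seed + 2L, {
    sizes <- sample(seq(min(term_size[1], length(universe)),
                        min(term_size[2], length(universe))),
                    n_terms, replace = TRUE)
    genes <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      s <- sizes[i]
      if (i <= enriched_terms) {
        k <- min(round(enriched_fraction * s), length(planted))
        rest <- setdiff(universe, planted)
        genes[[i]] <- c(sample(planted, k),
                        sample(rest, min(s - k, length(rest))))
      } else {
        genes[[i]] <- sample(universe, s)
      }
    }
    db <- list(term_id = sprintf("SET%04d", seq_len(n_terms)),
               description = ifelse(seq_len(n_terms) <= enriched_terms,
                                    "planted enriched term", "background term"),
               genes = genes)
    class(db) <- "gene_set_db"
    if (!is.null(path)) write_gmt(db, path)
    db
  })
}

#' Write a ground-truth table as TSV
#' @param truth Truth table from [generate_beta()].
#' @param path Output file path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
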