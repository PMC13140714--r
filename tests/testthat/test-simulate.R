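test_that("manifest generation respects degenerate and sampled island proportions", {
  props <- c(Island = 0, N_Shore = 0, S_Shore = 0, N_Shelf = 0, S_Shelf = 0, OpenSea = 1)
  cfg <- sim_config(n_probes = 100, island_proportions = props, seed = 1)
  man <- generate_manifest(cfg)
  expect_true(all(man$Relation_to_Island == "OpenSea"))

  # same seed -> byte-identical; different seed -> differs
  expect_identical(man, generate_manifest(cfg))
  cfg2 <- sim_config(n_probes = 100, island_proportions = props, seed = 2)
  expect_false(identical(generate_manifest(cfg2)$CHR, man$CHR))

  # binomial oracle: 10,000 probes at 0.3/0.7 within 3 binomial sd
  props37 <- c(Island = 0.3, N_Shore = 0, S_Shore = 0, N_Shelf = 0,
               S_Shelf = 0, OpenSea = 0.7)
  big <- generate_manifest(sim_config(n_probes = 10000, island_proportions = props37,
                                      seed = 42))
  n_island <- sum(big$Relation_to_Island == "Island")
  sd3 <- 3 * sqrt(10000 * 0.3 * 0.7)
  expect_lt(abs(n_island - 3000), sd3)
  expect_lt(abs(sum(big$Relation_to_Island == "OpenSea") - 7000), sd3)

  bad <- props; bad["OpenSea"] <- 0.5
  expect_error(sim_config(n_probes = 10, island_proportions = bad), "sum to 1")
})

test_that("manifest has many-to-many probe-gene structure and unannotated probes", {
  man <- generate_manifest(sim_config(n_probes = 3000, seed = 9))
  genes <- split_semicolon(man$UCSC_RefGene_Name)
  expect_gt(sum(lengths(genes) == 0), 0)      # unannotated probes exist
  expect_gt(sum(lengths(genes) >= 2), 0)      # probes mapping to >= 2 genes
  tab <- table(unlist(genes))
  expect_gt(sum(tab >= 2), 0)                 # genes owning >= 2 probes
  # gene-structure groups align index-wise with gene symbols
  groups <- split_semicolon(man$UCSC_RefGene_Group)
  expect_identical(lengths(groups), lengths(genes))
  # RefSeq ids mirror gene symbols
  refseq <- split_semicolon(man$RefSeq_ID)
  expect_identical(lengths(refseq), lengths(genes))
})

test_that("generate_beta honours range, null configuration and determinism", {
  cfg0 <- sim_config(n_probes = 300, frac_dmp = 0, frac_crossing_low_high = 0,
                     frac_crossing_high_low = 0, seed = 3)
  man <- generate_manifest(cfg0)
  sim <- generate_beta(man, cfg0)
  expect_false(any(sim$truth$is_dmp))
  expect_equal(sim$truth$true_mean_beta_control, sim$truth$true_mean_beta_case)
  v <- sim$beta[!is.na(sim$beta)]
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(sim$truth$probe_id, man$IlmnID)

  sim2 <- generate_beta(man, cfg0)
  expect_identical(sim, sim2)

  expect_error(generate_beta(man, sim_config(n_probes = 10, n_control = 2,
                                             n_case = 1, n_datasets = 1)),
               "at least 4 samples")
})

test_that("planted M-scale means map back to the stored true beta means", {
  cfg <- sim_config(n_probes = 400, seed = 8)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  expect_equal(m_to_beta(sim$truth$true_mean_m_control),
               sim$truth$true_mean_beta_control, tolerance = 1e-12)
  expect_equal(m_to_beta(sim$truth$true_mean_m_case),
               sim$truth$true_mean_beta_case, tolerance = 1e-12)
  # crossing probes have true means on opposite sides of 0.5
  lh <- sim$truth$planted_class == "low_to_high"
  expect_true(all(sim$truth$true_mean_beta_control[lh] < 0.5))
  expect_true(all(sim$truth$true_mean_beta_case[lh] >= 0.5))
  hl <- sim$truth$planted_class == "high_to_low"
  expect_true(all(sim$truth$true_mean_beta_control[hl] >= 0.5))
  expect_true(all(sim$truth$true_mean_beta_case[hl] < 0.5))
})

test_that("observed missingness tracks missing_rate for ordinary probes", {
  cfg <- sim_config(n_probes = 2000, missing_rate = 0.05,
                    frac_high_missing_probes = 0.01, seed = 13)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  ordinary <- !sim$truth$high_missing
  obs <- mean(is.na(sim$beta[ordinary, ]))
  n_cells <- sum(ordinary) * ncol(sim$beta)
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(obs - 0.05), 3 * se)
})

test_that("sample sheet partitions both groups into dataset blocks", {
  cfg <- sim_config(n_probes = 50, seed = 4)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  expect_equal(sum(sim$sheet$group == "Control"), 34)
  expect_equal(sum(sim$sheet$group == "Periodontitis"), 31)
  expect_equal(length(unique(sim$sheet$dataset_id)), 3)
  by_ds <- table(sim$sheet$dataset_id, sim$sheet$group)
  expect_true(all(by_ds > 0))
})

test_that("GMT generation round-trips and plants detectable enrichment", {
  cfg <- sim_config(n_probes = 1000, seed = 21)
  man <- generate_manifest(cfg)
  sim <- generate_beta(man, cfg)
  db <- generate_gmt(man, cfg, n_terms = 20, enriched_terms = 3, truth = sim$truth)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  back <- read_gmt(path)
  expect_identical(back$term_id, db$term_id)
  expect_identical(back$genes, db$genes)

  expect_error(generate_gmt(man, cfg, n_terms = 2, enriched_terms = 3,
                            truth = sim$truth), "n_terms")

  # single term over the full universe: RichFactor 1 with the universe as query
  universe <- unique(unlist(split_semicolon(man$UCSC_RefGene_Name)))
  full <- structure(list(term_id = "ALL", description = "all",
                         genes = list(universe)), class = "gene_set_db")
  rec <- ora_test(universe, full, universe, pvalue_cutoff = 1, qvalue_cutoff = 1)
  expect_equal(rec$rich_factor, 1)
  expect_equal(rec$fold_enrichment, 1)
})

test_that("planted terms beat size-matched random terms in ORA across seeds", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_probes = 800, seed = seed)
    man <- generate_manifest(cfg)
    sim <- generate_beta(man, cfg)
    db <- generate_gmt(man, cfg, n_terms = 2, enriched_terms = 1,
                       truth = sim$truth, term_size = c(30L, 30L))
    # query: genes of planted differential probes, as the analysis would find
    dmp_genes <- unique(unlist(split_semicolon(
      man$UCSC_RefGene_Name[man$IlmnID %in% sim$truth$probe_id[sim$truth$is_dmp]])))
    universe <- unique(unlist(split_semicolon(man$UCSC_RefGene_Name)))
    rec <- ora_test(dmp_genes, db, universe, pvalue_cutoff = 1, qvalue_cutoff = 1)
    p_planted <- rec$p_value[rec$term_id == "SET0001"]
    p_random <- rec$p_value[rec$term_id == "SET0002"]
    if (length(p_planted) && length(p_random) && p_planted < p_random)
      wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
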