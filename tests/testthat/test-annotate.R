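test_that("ordered_categories returns the canonical fixed enumerations", {
  ord <- ordered_categories()
  expect_equal(ord$island[6], "OpenSea")          # 0-based index 5
  expect_equal(ord$refgene[1], "TSS200")
  expect_equal(ord$island[7], "Unknown")
  expect_equal(ord$refgene[7], "Unknown")
  expect_equal(length(ord$island), 7L)
  expect_equal(length(ord$refgene), 7L)
})

test_that("attach_annotation explodes mappings and backfills Unknown", {
  tab <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4"),
                    significant = TRUE, stringsAsFactors = FALSE)
  man <- make_manifest(c("cg1", "cg2", "cg3"),
                       genes = c("A;B", "C", ""),
                       groups = c("Body;TSS200", "5'UTR", ""),
                       relation = c("Island", "N_Shore", ""))
  ann <- attach_annotation(tab, man)          # cg4 absent from the manifest
  expect_equal(nrow(ann), 5L)                 # 2 + 1 + 1 + 1 assignments
  a1 <- ann[ann$probe_id == "cg1", ]
  expect_identical(a1$gene_symbol, c("A", "B"))
  expect_identical(a1$refgene_group, c("Body", "TSS200"))
  expect_identical(ann$refgene_group[ann$probe_id == "cg3"], "Unknown")
  expect_identical(ann$relation_to_island[ann$probe_id == "cg3"], "Unknown")
  expect_identical(ann$relation_to_island[ann$probe_id == "cg4"], "Unknown")
  expect_identical(ann$gene_symbol[ann$probe_id == "cg4"], "")

  # join preserves record count under one-to-one mapping
  simple <- make_manifest(c("cg1", "cg2", "cg3", "cg4"), genes = "X", groups = "Body")
  expect_equal(nrow(attach_annotation(tab, simple)), nrow(tab))

  dup <- rbind(man, man[1, ])
  expect_error(attach_annotation(tab, dup), "duplicate manifest rows")
})

test_that("crosstab counts match brute-force enumeration on a toy input", {
  # 5 probes with hand-assigned annotation, states and changes
  tab <- data.frame(
    probe_id = sprintf("cg%d", 1:5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    mean_beta_control = c(0.3, 0.3, 0.7, 0.6, 0.2),
    mean_beta_case = c(0.6, 0.55, 0.3, 0.7, 0.9),
    stringsAsFactors = FALSE)
  dirs <- classify_direction(tab)
  man <- make_manifest(tab$probe_id,
                       genes = c("A", "A;B", "C", "", "D"),
                       groups = c("Body", "Body;TSS200", "5'UTR", "", "Body"),
                       relation = c("Island", "Island", "OpenSea", "S_Shelf", "Island"))
  ann <- attach_annotation(tab, man)
  ct <- crosstab(ann, dirs)

  # brute force over the significant assignments only
  sig_ann <- ann[ann$significant, ]
  sig_ann$state_case <- dirs$state_case[match(sig_ann$probe_id, dirs$probe_id)]
  sig_ann$change_class <- dirs$change_class[match(sig_ann$probe_id, dirs$probe_id)]
  oracle <- crosstab_bruteforce(sig_ann)
  change_key <- c("High-methylation" = "low_to_high", "Low-methylation" = "high_to_low")
  for (i in seq_len(nrow(ct))) {
    st <- if (ct$Methylation_state[i] == "High-methylation") "high" else "low"
    key <- paste(ct$Relation_to_Island[i], ct$UCSC_RefGene_Group[i], st,
                 change_key[[ct$Methylation_state[i]]], sep = "|")
    expect_equal(ct$change_count[i], oracle[[key]] %||% 0L,
                 info = key)
  }
  # partition: state counts over all strata sum to total assignments
  expect_equal(sum(ct$state_count), attr(ct, "total_assignments"))
  expect_equal(attr(ct, "total_assignments"), nrow(sig_ann))
  expect_equal(sum(ct$state_percent), 100, tolerance = 1e-9)

  # island-level header percentages are constant per island and sum to 100
  hdr <- unique(ct[, c("Relation_to_Island", "island_percent")])
  expect_equal(sum(hdr$island_percent), 100, tolerance = 0.05)

  # invariance under row permutation of the input
  set.seed(1)
  ct2 <- crosstab(ann[sample(nrow(ann)), ], dirs[sample(nrow(dirs)), ])
  expect_equal(ct2, ct, ignore_attr = TRUE)
})

test_that("crosstab places top-gene labels only in exactly matching cells", {
  tab <- data.frame(probe_id = c("cg1", "cg2"), significant = TRUE,
                    logFC = c(1, 1.2),
                    mean_beta_control = c(0.3, 0.4), mean_beta_case = c(0.6, 0.7),
                    stringsAsFactors = FALSE)
  dirs <- classify_direction(tab)
  man <- make_manifest(c("cg1", "cg2"), genes = c("A", "B"),
                       groups = c("Body", "TSS200"),
                       relation = c("Island", "OpenSea"))
  ann <- attach_annotation(tab, man)
  top <- rank_top_genes(tab, dirs, man, n_top = 20)
  ct <- crosstab(ann, dirs, top)
  labelled <- ct[nzchar(ct$UCSC_RefGene_Name), ]
  expect_equal(nrow(labelled), 2L)
  rowA <- labelled[labelled$UCSC_RefGene_Name == "A", ]
  expect_identical(rowA$Relation_to_Island, "Island")
  expect_identical(rowA$UCSC_RefGene_Group, "Body")
  expect_identical(rowA$Methylation_state, "High-methylation")
  # every placed label has a qualifying CpG whose annotation matches the cell
  for (i in seq_len(nrow(labelled))) {
    genes <- strsplit(labelled$UCSC_RefGene_Name[i], ";")[[1]]
    for (g in genes) {
      hit <- ann$gene_symbol == g &
        ann$relation_to_island == labelled$Relation_to_Island[i] &
        ann$refgene_group == labelled$UCSC_RefGene_Group[i]
      expect_true(any(hit))
    }
  }
})

test_that("crosstab TSV rendering uses 2 decimals with the sub-threshold convention", {
  expect_identical(methcross:::format_percent(0.004, 5L), "< 0.01")
  expect_identical(methcross:::format_percent(0, 0L), "0.00")       # exact zero cell
  expect_identical(methcross:::format_percent(0.02, 3L), "0.02")
  expect_identical(methcross:::format_percent(19.857, 100L), "19.86")

  tab <- data.frame(probe_id = "cg1", significant = TRUE,
                    mean_beta_control = 0.3, mean_beta_case = 0.6,
                    stringsAsFactors = FALSE)
  dirs <- classify_direction(tab)
  ann <- attach_annotation(tab, make_manifest("cg1", genes = "A", groups = "Body",
                                              relation = "Island"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_crosstab_tsv(crosstab(ann, dirs), tmp)
  out <- read.table(tmp, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  expect_identical(names(out)[1], "Relation_to_Island")
  expect_true(any(grepl("^Island \\(100\\.00%\\)$", out$Relation_to_Island)))
  expect_false(any(grepl("< 0.01", out$Percent_of_total[out$CpG_count == "0"])))
})
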