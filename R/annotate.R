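# Manifest annotation of DMP records and the stratified island-relation x
# gene-structure x state x change cross-tabulation.

#' Canonical category orders for the cross-tabulation
#'
#' CpG-island relation categories ordered by proximity to the island (island,
#' north/south shores within 2 kb, north/south shelves 2-4 kb outside the
#' shores, open sea beyond), and gene-structure categories ordered by
#' proximity to the transcription start site. Both end with `Unknown`, the
#' bucket for unannotated probes.
#'
#' @return List with `island` and `refgene` character vectors.
#' @export
ordered_categories <- function() {
  list(
    island = c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea", "Unknown"),
    refgene = c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR", "Unknown")
  )
}

#' Attach manifest annotation to per-probe records
#'
#' Left-join on probe id, exploded to CpG-feature assignments: a probe with k
#' retained (gene, gene-structure) pairs yields k rows; a probe with an empty
#' gene list yields one row with `Unknown` gene-structure group; a probe
#' absent from the manifest gets `Unknown` island relation and `Unknown`
#' group. Blank categories are normalised to `Unknown`.
#'
#' @param dmps `dmpfit` object or per-probe table with a `probe_id` column.
#' @param manifest Probe annotation manifest (one row per probe).
#' @return The input rows replicated per assignment, with added columns
#'   `gene_symbol` (`""` when unannotated), `refgene_group`,
#'   `relation_to_island`.
#' @export
attach_annotation <- function(dmps, manifest) {
  tab <- if (inherits(dmps, "dmpfit")) dmps$table else dmps
  stopifnot("probe_id" %in% names(tab))
  if (anyDuplicated(manifest$IlmnID))
    stopf("duplicate manifest rows for probe(s): %s",
          paste(unique(manifest$IlmnID[duplicated(manifest$IlmnID)]), collapse = ", "))
  mi <- match(tab$probe_id, manifest$IlmnID)
  relation <- manifest$Relation_to_Island[mi]
  relation[is.na(relation) | !nzchar(relation)] <- "Unknown"
  genes <- split_semicolon(manifest$UCSC_RefGene_Name[mi])
  groups <- split_semicolon(manifest$UCSC_RefGene_Group[mi])
  genes[is.na(mi)] <- list(character(0))
  groups[is.na(mi)] <- list(character(0))

  k <- pmax(lengths(genes), 1L)
  gene_symbol <- unlist(mapply(function(g, n) if (length(g)) g else "",
                               genes, k, SIMPLIFY = FALSE), use.names = FALSE)
  refgene_group <- unlist(mapply(function(g, gr, n) {
    if (!length(g)) return("Unknown")
    # manifest alignment convention: groups index-aligned with gene symbols
    out <- rep("Unknown", length(g))
    out[seq_len(min(length(g), length(gr)))] <- gr[seq_len(min(length(g), length(gr)))]
    out[!nzchar(out)] <- "Unknown"
    out
  }, genes, groups, k, SIMPLIFY = FALSE), use.names = FALSE)

  out <- tab[rep(seq_len(nrow(tab)), k), , drop = FALSE]
  out$gene_symbol <- gene_symbol
  out$refgene_group <- refgene_group
  out$relation_to_island <- rep(relation, k)
  rownames(out) <- NULL
  out
}

format_percent <- function(pct, count) {
  ifelse(count > 0 & pct < 0.005, "< 0.01", sprintf("%.2f", pct))
}

#' Stratified cross-tabulation of significant CpG-feature assignments
#'
#' Counts CpG-feature assignments (one per retained probe-gene mapping, one
#' per unannotated probe) among significant CpGs, stratified by CpG-island
#' relation, gene-structure group, case-group methylation state and
#' threshold-crossing change class. Rows are emitted in the canonical category
#' orders, one High-methylation and one Low-methylation row per stratum; the
#' High state pairs with the low-to-high crossing (and vice versa) since the
#' state column reports the case group. Percentages use the total number of
#' significant assignments as denominator; positive percentages below 0.005
#' render as `"< 0.01"`.
#'
#' @param annotated Assignments from [attach_annotation()] (must carry
#'   `significant`; only significant rows are tabulated).
#' @param directions Direction records from [classify_direction()].
#' @param top_genes Optional ranking from [rank_top_genes()]; its gene symbols
#'   label the cells where their qualifying CpGs fall.
#' @return Data frame with columns `Relation_to_Island, island_percent,
#'   UCSC_RefGene_Group, Methylation_state, state_count, state_percent,
#'   Methylation_Status_Change, change_count, change_percent,
#'   UCSC_RefGene_Name`, plus attribute `total_assignments`.
#' @export
crosstab <- function(annotated, directions, top_genes = NULL) {
  stopifnot(all(c("probe_id", "relation_to_island", "refgene_group") %in% names(annotated)))
  if ("significant" %in% names(annotated))
    annotated <- annotated[annotated$significant %in% TRUE, , drop = FALSE]
  di <- match(annotated$probe_id, directions$probe_id)
  annotated$state_case <- directions$state_case[di]
  annotated$change_class <- directions$change_class[di]
  total <- nrow(annotated)

  ord <- ordered_categories()
  states <- c(high = "High-methylation", low = "Low-methylation")
  changes <- c(high = "Control low -> Periodontitis high",
               low = "Control high -> Periodontitis low")
  change_key <- c(high = "low_to_high", low = "high_to_low")

  island_counts <- vapply(ord$island, function(isl)
    sum(annotated$relation_to_island == isl), integer(1))

  rows <- list()
  for (isl in ord$island) {
    a_isl <- annotated[annotated$relation_to_island == isl, , drop = FALSE]
    for (grp in ord$refgene) {
      a <- a_isl[a_isl$refgene_group == grp, , drop = FALSE]
      for (st in c("high", "low")) {
        n_state <- sum(a$state_case == st, na.rm = TRUE)
        n_change <- sum(a$change_class == change_key[[st]], na.rm = TRUE)
        labels <- character(0)
        if (!is.null(top_genes) && nrow(top_genes)) {
          tg <- top_genes[top_genes$direction == change_key[[st]], , drop = FALSE]
          for (j in seq_len(nrow(tg))) {
            cpgs <- strsplit(tg$cpg_ids[j], ";", fixed = TRUE)[[1L]]
            hit <- a$gene_symbol == tg$gene_symbol[j] &
              a$probe_id %in% cpgs &
              a$change_class %in% change_key[[st]]
            if (any(hit, na.rm = TRUE)) labels <- c(labels, tg$gene_symbol[j])
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          Relation_to_Island = isl,
          island_percent = if (total) 100 * island_counts[[isl]] / total else 0,
          UCSC_RefGene_Group = grp,
          Methylation_state = states[[st]],
          state_count = n_state,
          state_percent = if (total) 100 * n_state / total else 0,
          Methylation_Status_Change = changes[[st]],
          change_count = n_change,
          change_percent = if (total) 100 * n_change / total else 0,
          UCSC_RefGene_Name = paste(sort(unique(labels)), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_assignments") <- total
  out
}

#' Write the cross-tabulation as a rendered TSV
#'
#' Renders the percentage columns to two decimals with the `"< 0.01"`
#' convention for positive sub-threshold values; island-level percentages are
#' attached to the island label of each stratum.
#'
#' @param ct Table from [crosstab()].
#' @param path Output file path.
#' @export
write_crosstab_tsv <- function(ct, path) {
  out <- data.frame(
    Relation_to_Island = sprintf("%s (%.2f%%)", ct$Relation_to_Island, ct$island_percent),
    UCSC_RefGene_Group = ct$UCSC_RefGene_Group,
    Methylation_state = ct$Methylation_state,
    Percent_of_total = format_percent(ct$state_percent, ct$state_count),
    Methylation_Status_Change = ct$Methylation_Status_Change,
    Percent_of_change = format_percent(ct$change_percent, ct$change_count),
    CpG_count = ct$change_count,
    UCSC_RefGene_Name = ct$UCSC_RefGene_Name,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
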