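# Threshold-crossing directionality: group-mean beta states relative to the
# 0.5 boundary and top-gene ranking by aggregated logFC within direction.

#' Group-wise mean beta values per probe
#'
#' Means are taken over observed entries only; a probe with no observed value
#' in either group is flagged unclassifiable (`NA` mean).
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @return Data frame `probe_id, mean_beta_control, mean_beta_case, n_obs_control,
#'   n_obs_case`.
#' @export
group_mean_beta <- function(beta, sheet) {
  validate_beta_matrix(beta)
  sheet <- check_sheet_matches(beta, sheet)
  is_case <- sheet$group == "Periodontitis"
  if (!any(is_case) || all(is_case)) stopf("both groups must be present")
  nc <- rowSums(!is.na(beta[, !is_case, drop = FALSE]))
  nk <- rowSums(!is.na(beta[, is_case, drop = FALSE]))
  mc <- rowMeans(beta[, !is_case, drop = FALSE], na.rm = TRUE)
  mk <- rowMeans(beta[, is_case, drop = FALSE], na.rm = TRUE)
  mc[nc == 0L] <- NA_real_
  mk[nk == 0L] <- NA_real_
  data.frame(probe_id = rownames(beta), mean_beta_control = mc,
             mean_beta_case = mk, n_obs_control = nc, n_obs_case = nk,
             row.names = NULL, stringsAsFactors = FALSE)
}

beta_state <- function(mean_beta, cutoff = 0.5) {
  ifelse(is.na(mean_beta), NA_character_,
         ifelse(mean_beta >= cutoff, "high", "low"))
}

#' Classify the group-level methylation change of a CpG
#'
#' Each group mean is assigned a high-methylation state (beta >= 0.5,
#' boundary inclusive) or low-methylation state (beta < 0.5). A change class
#' is the pure function of the two states: `low_to_high` (control low, case
#' high), `high_to_low` (control high, case low), or `stable_high` /
#' `stable_low` when the state does not cross the boundary. A missing mean
#' yields `NA` (unclassifiable), never a silent drop.
#'
#' @param mean_control,mean_case Group-mean beta vectors.
#' @param cutoff State boundary (default 0.5).
#' @return Character vector of change classes.
#' @examples
#' classify_change(0.325088974, 0.550743732)  # low_to_high
#' classify_change(0.585531722, 0.356951427)  # high_to_low
#' @export
classify_change <- function(mean_control, mean_case, cutoff = 0.5) {
  sc <- beta_state(mean_control, cutoff)
  sk <- beta_state(mean_case, cutoff)
  ifelse(is.na(sc) | is.na(sk), NA_character_,
    ifelse(sc == "low" & sk == "high", "low_to_high",
      ifelse(sc == "high" & sk == "low", "high_to_low",
        ifelse(sk == "high", "stable_high", "stable_low"))))
}

#' Direction records for every probe of a fit
#'
#' Convenience wrapper combining [group_mean_beta()] states and
#' [classify_change()] for the probes of a fitted model or a beta matrix.
#'
#' @param x A `dmpfit` object, or a data frame carrying `probe_id,
#'   mean_beta_control, mean_beta_case`.
#' @param cutoff State boundary (default 0.5).
#' @return Data frame `probe_id, mean_beta_control, mean_beta_case,
#'   state_control, state_case, change_class`.
#' @export
classify_direction <- function(x, cutoff = 0.5) {
  tab <- if (inherits(x, "dmpfit")) x$table else x
  stopifnot(all(c("probe_id", "mean_beta_control", "mean_beta_case") %in% names(tab)))
  data.frame(
    probe_id = tab$probe_id,
    mean_beta_control = tab$mean_beta_control,
    mean_beta_case = tab$mean_beta_case,
    state_control = beta_state(tab$mean_beta_control, cutoff),
    state_case = beta_state(tab$mean_beta_case, cutoff),
    change_class = classify_change(tab$mean_beta_control, tab$mean_beta_case, cutoff),
    stringsAsFactors = FALSE
  )
}

#' Rank genes by aggregated |logFC| within each crossing direction
#'
#' Restricted to significant probes whose change class is a threshold
#' crossing. Probe-to-gene mappings are exploded (a probe annotated to k genes
#' contributes to k genes, all mappings retained); per (gene, direction) the
#' qualifying probes' logFC and group-mean betas are averaged and the
#' probes' ids collected. Within each direction genes are sorted by
#' `|mean_logFC|` descending (ties by gene symbol) and the top `n_top`
#' returned. Alternatively `rank_by = "max"` ranks by the largest per-CpG
#' |logFC| within the gene.
#'
#' @param dmps `dmpfit` object or DMP table with `probe_id, logFC, significant`.
#' @param directions Direction records from [classify_direction()].
#' @param manifest Probe annotation manifest.
#' @param n_top Genes returned per direction (default 20).
#' @param rank_by `"mean"` (default) or `"max"` per-gene |logFC| ranking key.
#' @return Data frame `direction, gene_symbol, mean_logFC, mean_beta_control,
#'   mean_beta_case, n_cpgs, cpg_ids, refseq_ids` (multi-values
#'   semicolon-delimited), ordered by direction then rank.
#' @export
rank_top_genes <- function(dmps, directions, manifest, n_top = 20L,
                           rank_by = c("mean", "max")) {
  rank_by <- match.arg(rank_by)
  tab <- if (inherits(dmps, "dmpfit")) dmps$table else dmps
  stopifnot(all(c("probe_id", "logFC", "significant") %in% names(tab)))

  dir <- directions$change_class[match(tab$probe_id, directions$probe_id)]
  qual <- tab$significant %in% TRUE & dir %in% c("low_to_high", "high_to_low")
  if (!any(qual)) {
    warnf("no significant threshold-crossing probes; returning empty ranking")
    return(data.frame(direction = character(0), gene_symbol = character(0),
                      mean_logFC = numeric(0), mean_beta_control = numeric(0),
                      mean_beta_case = numeric(0), n_cpgs = integer(0),
                      cpg_ids = character(0), refseq_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  q <- tab[qual, , drop = FALSE]
  q$direction <- dir[qual]
  di <- match(q$probe_id, directions$probe_id)
  q$mean_beta_control <- directions$mean_beta_control[di]
  q$mean_beta_case <- directions$mean_beta_case[di]

  mi <- match(q$probe_id, manifest$IlmnID)
  genes <- split_semicolon(manifest$UCSC_RefGene_Name[mi])
  refseq <- split_semicolon(manifest$RefSeq_ID[mi])
  ng <- lengths(genes)
  has <- ng > 0L
  if (!any(has)) {
    warnf("no qualifying probe maps to a gene; returning empty ranking")
    return(rank_top_genes(tab[0, ], directions, manifest, n_top))
  }
  # explode probe -> gene mappings; refseq ids ride along per probe
  exp <- data.frame(
    gene_symbol = unlist(genes[has]),
    probe_id = rep(q$probe_id[has], ng[has]),
    direction = rep(q$direction[has], ng[has]),
    logFC = rep(q$logFC[has], ng[has]),
    mean_beta_control = rep(q$mean_beta_control[has], ng[has]),
    mean_beta_case = rep(q$mean_beta_case[has], ng[has]),
    refseq = rep(join_semicolon(refseq[has]), ng[has]),
    stringsAsFactors = FALSE
  )
  key <- paste(exp$direction, exp$gene_symbol, sep = "\r")
  agg <- lapply(split(exp, key), function(d) data.frame(
    direction = d$direction[1L],
    gene_symbol = d$gene_symbol[1L],
    mean_logFC = mean(d$logFC),
    max_abs_logFC = max(abs(d$logFC)),
    mean_beta_control = mean(d$mean_beta_control),
    mean_beta_case = mean(d$mean_beta_case),
    n_cpgs = nrow(d),
    cpg_ids = paste(sort(unique(d$probe_id)), collapse = ";"),
    refseq_ids = paste(unique(unlist(strsplit(d$refseq, ";", fixed = TRUE))),
                       collapse = ";"),
    stringsAsFactors = FALSE
  ))
  agg <- do.call(rbind, agg)
  rownames(agg) <- NULL
  out <- do.call(rbind, lapply(c("low_to_high", "high_to_low"), function(dd) {
    g <- agg[agg$direction == dd, , drop = FALSE]
    if (!nrow(g)) return(g)
    rank_key <- if (rank_by == "mean") abs(g$mean_logFC) else g$max_abs_logFC
    g <- g[order(-rank_key, g$gene_symbol), , drop = FALSE]
    utils::head(g, n_top)
  }))
  rownames(out) <- NULL
  out$max_abs_logFC <- NULL
  out
}

#' Write the top-gene ranking as TSV
#' @param top Table from [rank_top_genes()].
#' @param path Output file path.
#' @export
write_top_genes_tsv <- function(top, path) {
  utils::write.table(top, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
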