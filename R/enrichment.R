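# Hypergeometric over-representation analysis over GMT gene sets with the
# full ratio-statistic vocabulary: GeneRatio k/n, BgRatio K/N, RichFactor k/K,
# FoldEnrichment (k/n)/(K/N), and the finite-population z-score.

#' Ratio statistics for one over-representation contingency
#'
#' For an overlap of `k` query genes with a term of `K` genes in a universe of
#' `N`, with query size `n`: `gene_ratio = k/n`, `bg_ratio = K/N`,
#' `rich_factor = k/K`, `fold_enrichment = (k/n)/(K/N)`, and the z-score of
#' `k` against its hypergeometric mean `nK/N` with the finite-population
#' variance `n (K/N)(1 - K/N)(N - n)/(N - 1)`.
#'
#' @param k,n,K,N Overlap count, query size, term size, universe size
#'   (vectorised; must satisfy `0 <= k <= min(n, K)` and `N >= max(n, K)`).
#' @return Data frame `gene_ratio, bg_ratio, rich_factor, fold_enrichment,
#'   z_score`; statistics needing a positive `K` or `n` are `NA` when the
#'   divisor is zero.
#' @examples
#' derive_statistics(327, 14754, 337, 18805)
#' @export
derive_statistics <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, len); n <- rep_len(n, len)
  K <- rep_len(K, len); N <- rep_len(N, len)
  if (any(k < 0 | k > pmin(n, K) | N < pmax(n, K)))
    stopf("contingency bounds violated: need 0 <= k <= min(n, K) and N >= max(n, K)")
  gene_ratio <- ifelse(n > 0, k / n, NA_real_)
  bg_ratio <- K / N
  rich_factor <- ifelse(K > 0, k / K, NA_real_)
  fold_enrichment <- ifelse(n > 0 & K > 0, gene_ratio / bg_ratio, NA_real_)
  v <- n * bg_ratio * (1 - bg_ratio) * (N - n) / (N - 1)
  z_score <- ifelse(v > 0, (k - n * bg_ratio) / sqrt(v), NA_real_)
  data.frame(gene_ratio = gene_ratio, bg_ratio = bg_ratio,
             rich_factor = rich_factor, fold_enrichment = fold_enrichment,
             z_score = z_score)
}

#' Hypergeometric over-representation test over a gene-set collection
#'
#' Per term: `K` = term genes in the universe, `k` = term genes in the query,
#' `n` = query genes in the universe; the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution (population `N`, successes
#' `K`, draws `n`). BH adjustment is applied across tested terms; the q-value
#' column defaults to the BH value. Query genes outside the universe are
#' dropped with a message; terms with `K = 0` are skipped.
#'
#' @param query Character vector of query gene symbols.
#' @param db A `gene_set_db` ([read_gmt()] / [generate_gmt()]).
#' @param universe Background gene symbols; defaults to the union of all genes
#'   in `db`.
#' @param pvalue_cutoff,qvalue_cutoff Reporting filters (defaults 0.05 / 0.2);
#'   set both to 1 to keep every tested term.
#' @return Data frame with one row per surviving term: `term_id, description,
#'   k, n, K, N, p_value, p_adjusted, q_value, gene_ratio, bg_ratio,
#'   rich_factor, fold_enrichment, z_score, overlap_genes`
#'   (semicolon-delimited), sorted by p-value.
#' @export
ora_test <- function(query, db, universe = NULL,
                     pvalue_cutoff = 0.05, qvalue_cutoff = 0.2) {
  stopifnot(inherits(db, "gene_set_db"))
  if (is.null(universe)) universe <- unique(unlist(db$genes))
  universe <- unique(universe)
  if (!length(universe)) stopf("universe is empty")
  query <- unique(query)
  if (!length(query)) stopf("query gene set is empty")
  dropped <- sum(!query %in% universe)
  if (dropped) {
    message(sprintf("dropping %d query gene(s) outside the universe", dropped))
    query <- query[query %in% universe]
    if (!length(query)) stopf("no query gene remains inside the universe")
  }
  n <- length(query)
  N <- length(universe)
  terms <- lapply(db$genes, intersect, universe)
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(g %in% query), integer(1))
  keep <- K > 0L
  # upper-tail hypergeometric: P(X >= k)
  p <- stats::phyper(k[keep] - 1L, K[keep], N - K[keep], n, lower.tail = FALSE)
  padj <- adjust_bh(p)
  stats <- derive_statistics(k[keep], n, K[keep], N)
  out <- data.frame(
    term_id = db$term_id[keep],
    description = db$description[keep],
    k = k[keep], n = n, K = K[keep], N = N,
    p_value = p, p_adjusted = padj, q_value = padj,
    stats,
    overlap_genes = vapply(terms[keep], function(g)
      paste(sort(intersect(g, query)), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  keep_all <- pvalue_cutoff >= 1 & qvalue_cutoff >= 1
  if (!keep_all)
    out <- out[out$p_adjusted < pvalue_cutoff & out$q_value < qvalue_cutoff, , drop = FALSE]
  out <- out[order(out$p_value, out$p_adjusted, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top enriched terms
#'
#' Sorts surviving records by p-value (ties by adjusted p, then term id) and
#' returns the first `n` with a `rank` column 1..n.
#'
#' @param records Table from [ora_test()].
#' @param n Number of terms (default 20).
#' @export
top_terms <- function(records, n = 20L) {
  out <- records[order(records$p_value, records$p_adjusted, records$term_id), ,
                 drop = FALSE]
  out <- utils::head(out, n)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Intersect enrichment overlaps with the top differentially methylated genes
#'
#' Adds a `top_gene_overlap` column: the overlap genes of each term that are
#' also among the top-ranked differentially methylated genes. Empty overlaps
#' render blank.
#'
#' @param records Table from [ora_test()] / [top_terms()].
#' @param top_genes Ranking from [rank_top_genes()] (or a character vector of
#'   gene symbols).
#' @export
intersect_top_genes <- function(records, top_genes) {
  symbols <- if (is.character(top_genes)) top_genes else top_genes$gene_symbol
  records$top_gene_overlap <- vapply(
    strsplit(records$overlap_genes, ";", fixed = TRUE),
    function(g) paste(intersect(g, symbols), collapse = "/"), "")
  records
}

#' Write an enrichment table as TSV
#'
#' Columns follow the conventional enrichment-report vocabulary: `rank, ID,
#' Description, geneID` (slash-delimited top-gene overlap), `pvalue, p.adjust,
#' qvalue, RichFactor, FoldEnrichment, zScore, GeneRatio` (`"k/n"`),
#' `BgRatio` (`"K/N"`), `Count`.
#'
#' @param records Table from [top_terms()], optionally after
#'   [intersect_top_genes()].
#' @param path Output file path.
#' @export
write_enrichment_tsv <- function(records, path) {
  out <- data.frame(
    rank = if ("rank" %in% names(records)) records$rank else seq_len(nrow(records)),
    ID = records$term_id,
    Description = records$description,
    geneID = if ("top_gene_overlap" %in% names(records)) records$top_gene_overlap else "",
    pvalue = records$p_value,
    p.adjust = records$p_adjusted,
    qvalue = records$q_value,
    RichFactor = records$rich_factor,
    FoldEnrichment = records$fold_enrichment,
    zScore = records$z_score,
    GeneRatio = sprintf("%d/%d", records$k, records$n),
    BgRatio = sprintf("%d/%d", records$K, records$N),
    Count = records$k,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
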