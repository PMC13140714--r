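#' Published top-gene directionality table
#'
#' Group-mean beta values, mean logFC, CpG ids and RefSeq ids for the top 20
#' threshold-crossing genes per direction reported by a published
#' gingival-tissue 450K methylation study of periodontitis (20 low-to-high
#' and 20 high-to-low crossings at the beta = 0.5 boundary). Shipped as a
#' plain-text fixture; useful as a worked example for [classify_change()].
#'
#' @return Data frame with columns `direction, gene_symbol, mean_logFC,
#'   mean_beta_control, mean_beta_case, cpg_ids, refseq_ids`.
#' @examples
#' tab <- published_top_genes()
#' table(classify_change(tab$mean_beta_control, tab$mean_beta_case))
#' @export
published_top_genes <- function() {
  path <- system.file("extdata", "top20_direction_means.tsv",
                      package = "methcross", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}
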