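# Plain-text readers/writers for the pipeline's artifact dialects.
# Beta matrix: TSV, first column probe_id, remaining columns one per sample.
# Sample sheet: CSV with sample_id, group, dataset_id.
# Manifest: TSV with Illumina 450K column vocabulary, multi-values ";"-packed.

#' Write a beta (or M) matrix as TSV
#'
#' @param mat Numeric matrix with probe ids as rownames and sample ids as
#'   colnames. Missing values are written as `NA`.
#' @param path Output file path.
#' @export
write_beta_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta (or M) matrix from TSV
#'
#' @param path File written by [write_beta_tsv()] (or any TSV with a probe id
#'   first column and one numeric column per sample).
#' @return Numeric matrix, probes in rows.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stopf("beta matrix TSV needs a probe id column plus samples: %s", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  validate_beta_matrix(mat, allow_m = TRUE)
  mat
}

#' Write a sample sheet as CSV
#' @param sheet Data frame with columns sample_id, group, dataset_id.
#' @param path Output file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#' @param path File with columns sample_id, group, dataset_id.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Write a probe annotation manifest as TSV
#' @param manifest Data frame in Illumina 450K manifest vocabulary
#'   (IlmnID, CHR, MAPINFO, UCSC_RefGene_Name, UCSC_RefGene_Group,
#'   Relation_to_Island, RefSeq_ID).
#' @param path Output file path.
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation manifest TSV
#' @param path File written by [write_manifest_tsv()].
#' @export
read_manifest_tsv <- function(path) {
  man <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c(IlmnID = "character"), fill = TRUE,
                           na.strings = "NA", quote = "")
  for (col in c("UCSC_RefGene_Name", "UCSC_RefGene_Group", "RefSeq_ID",
                "Relation_to_Island"))
    if (col %in% names(man)) man[[col]][is.na(man[[col]])] <- ""
  man
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @return A `gene_set_db`: list with `term_id`, `description` (character
#'   vectors) and `genes` (list of character vectors), one entry per term.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields: %s", path)
  db <- list(
    term_id = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(db$term_id)) stopf("duplicate term ids in GMT: %s", path)
  class(db) <- "gene_set_db"
  db
}

#' Write gene sets to a GMT file
#' @param db A `gene_set_db` as returned by [read_gmt()].
#' @param path Output file path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    db$term_id, db$description, db$genes)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("Gene set collection: %d terms, %d distinct genes\n",
              length(x$term_id), length(unique(unlist(x$genes)))))
  invisible(x)
}
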