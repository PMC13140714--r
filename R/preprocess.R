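# Merging, missingness filtering and the beta -> M transform.

validate_beta_matrix <- function(mat, allow_m = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("beta matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stopf("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(mat))) stopf("duplicate sample ids in beta matrix")
  if (!allow_m) {
    v <- mat[!is.na(mat)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stopf("beta values must lie in [0, 1] or be missing")
  }
  invisible(mat)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "dataset_id")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet)))
    stopf("sample sheet needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stopf("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$group), c("Control", "Periodontitis"))
  if (length(bad))
    stopf("sample sheet group must be Control or Periodontitis (found: %s)",
          paste(bad, collapse = ", "))
  invisible(sheet)
}

check_sheet_matches <- function(mat, sheet) {
  if (!identical(sort(colnames(mat)), sort(sheet$sample_id)))
    stopf("sample sheet rows do not match matrix columns one-to-one")
  # align sheet to column order
  sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
}

#' Merge beta matrices from several datasets on shared probes
#'
#' Datasets profiled on the same array are merged into one CpG-by-sample
#' matrix over the probes common to all inputs. Probe order follows the first
#' matrix; columns are concatenated in input order, as are sample-sheet rows.
#'
#' @param matrices List of beta matrices (probes in rows, samples in columns).
#' @param sheets List of sample sheets, parallel to `matrices`.
#' @return List with elements `beta` (merged matrix) and `sheet` (merged
#'   sample sheet, rows aligned with the matrix columns).
#' @examples
#' a <- matrix(c(.1, .2, .3, .4), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' b <- matrix(c(.5, .6), 2, 1, dimnames = list(c("cg2", "cg1"), "s3"))
#' sh <- function(ids, ds) data.frame(sample_id = ids, group = "Control",
#'                                    dataset_id = ds)
#' m <- merge_datasets(list(a, b), list(sh(c("s1", "s2"), "d1"), sh("s3", "d2")))
#' dim(m$beta)
#' @export
merge_datasets <- function(matrices, sheets) {
  if (!length(matrices)) stopf("need at least one matrix to merge")
  if (length(matrices) != length(sheets))
    stopf("matrices and sheets must have the same length")
  for (i in seq_along(matrices)) {
    validate_beta_matrix(matrices[[i]])
    validate_sample_sheet(sheets[[i]])
    sheets[[i]] <- check_sheet_matches(matrices[[i]], sheets[[i]])
  }
  all_samples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  if (anyDuplicated(all_samples))
    stopf("duplicate sample id across input datasets: %s",
          paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  probes <- rownames(matrices[[1L]])
  for (m in matrices[-1L]) probes <- probes[probes %in% rownames(m)]
  if (!length(probes)) stopf("probe intersection across datasets is empty")
  merged <- do.call(cbind, lapply(matrices, function(m) m[probes, , drop = FALSE]))
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL
  list(beta = merged, sheet = sheet)
}

#' Remove probes exceeding a missingness threshold
#'
#' Probes whose fraction of missing values across samples is strictly greater
#' than `max_missing_fraction` are removed; a probe at exactly the threshold
#' is retained. The sample set is unchanged.
#'
#' @param mat Beta matrix.
#' @param max_missing_fraction Maximum tolerated missing fraction per probe
#'   (default 0.8, i.e. probes with more than 80\% missing are dropped).
#' @return The filtered matrix, with attribute `n_removed` giving the number
#'   of dropped probes.
#' @export
filter_missing <- function(mat, max_missing_fraction = 0.8) {
  validate_beta_matrix(mat, allow_m = TRUE)
  if (!is_fraction(max_missing_fraction))
    stopf("max_missing_fraction must be a single value in [0, 1]")
  if (!nrow(mat)) stopf("empty matrix")
  frac <- rowMeans(is.na(mat))
  keep <- frac <= max_missing_fraction
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Transform beta values to M-values
#'
#' The logit2 transform `M = log2(beta / (1 - beta))`, the conventional
#' modelling scale for differential methylation: M-values are approximately
#' homoscedastic where beta values are variance-compressed near 0 and 1.
#' Values are clamped to `[epsilon, 1 - epsilon]` first so boundary betas map
#' to finite M; missing entries stay missing.
#'
#' @param mat Beta matrix.
#' @param epsilon Boundary clamp in (0, 0.5); default `1e-6`.
#' @return M-value matrix of the same shape and missingness pattern.
#' @examples
#' beta_to_m(matrix(c(0.5, 0.8), 1, 2,
#'                  dimnames = list("cg1", c("s1", "s2"))))
#' @export
beta_to_m <- function(mat, epsilon = 1e-6) {
  validate_beta_matrix(mat)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5)
    stopf("epsilon must be a single value in (0, 0.5)")
  clamped <- pmin(pmax(mat, epsilon), 1 - epsilon)
  m <- log2(clamped / (1 - clamped))
  dimnames(m) <- dimnames(mat)
  m
}
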