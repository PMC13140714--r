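# Volcano plot, per-probe Z-scores, hierarchical clustering, heatmap and PCA.

GROUP_COLORS <- c(Control = "blue", Periodontitis = "red")

#' Volcano plot of differential methylation results
#'
#' logFC on the x-axis against -log10 BH-adjusted p on the y-axis, all probes
#' plotted regardless of significance, with a horizontal dashed line at
#' `-log10(alpha)` (about 1.301 at the conventional 0.05) and deliberately no
#' vertical logFC threshold lines. Adjusted p-values are clipped at
#' `p_floor` before the log transform so the ordinate stays finite.
#'
#' @param dmps `dmpfit` object or table with `logFC` and `adj.P.Val`.
#' @param alpha Significance threshold drawn as the dashed line (default 0.05).
#' @param p_floor Clip for adjusted p before `-log10` (default `1e-300`).
#' @param file Optional output path (`.png` or `.svg`); when `NULL`, draws on
#'   the active device.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted coordinates.
#' @export
volcano <- function(dmps, alpha = 0.05, p_floor = 1e-300, file = NULL, ...) {
  tab <- if (inherits(dmps, "dmpfit")) dmps$table else dmps
  stopifnot(nrow(tab) > 0, all(c("logFC", "adj.P.Val") %in% names(tab)))
  y <- -log10(pmax(tab$adj.P.Val, p_floor))
  sig <- tab$adj.P.Val < alpha
  draw <- function() {
    graphics::plot(tab$logFC, y, pch = 16, cex = 0.3,
                   col = ifelse(sig, "red3", "grey50"),
                   xlab = "logFC (M-value, Periodontitis - Control)",
                   ylab = expression(-log[10] ~ "adjusted p"), ...)
    graphics::abline(h = -log10(alpha), lty = 2)
  }
  if (!is.null(file)) with_device(file, draw()) else draw()
  invisible(data.frame(logFC = tab$logFC, neg_log10_adj_p = y, significant = sig))
}

with_device <- function(file, code) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 1600, height = 1200, res = 200),
         svg = grDevices::svg(file, width = 8, height = 6),
         stopf("unsupported plot format: .%s (use .png or .svg)", ext))
  on.exit(grDevices::dev.off())
  force(code)
}

#' Randomly sample significant probes for visualisation
#'
#' Uniform sample without replacement, reproducible under `seed`. When `n`
#' meets or exceeds the population the full list is returned with a warning.
#'
#' @param probe_ids Character vector to sample from.
#' @param n Sample size (default 10000).
#' @param seed Integer seed.
#' @export
sample_significant <- function(probe_ids, n = 10000L, seed = 1L) {
  if (n >= length(probe_ids)) {
    if (n > length(probe_ids))
      warnf("requested %d probes but only %d available; returning all", n, length(probe_ids))
    return(probe_ids)
  }
  with_seed(seed, sample(probe_ids, n))
}

#' Standardise each probe row to Z-scores
#'
#' Per observed entry, `(value - row mean) / row sd` with the n-1 sample
#' standard deviation. Rows with fewer than 2 observed values or zero
#' variance are dropped (count in attribute `n_dropped`).
#'
#' @param beta Beta (or any numeric) matrix, probes in rows.
#' @return Z-score matrix; each retained row has mean 0 and sd 1.
#' @export
zscore_rows <- function(beta) {
  stopifnot(is.matrix(beta))
  mu <- rowMeans(beta, na.rm = TRUE)
  sd <- apply(beta, 1L, stats::sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(beta))
  keep <- n_obs >= 2L & !is.na(sd) & sd > 0
  z <- (beta[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  attr(z, "n_dropped") <- sum(!keep)
  z
}

#' Hierarchical clustering of probes or samples
#'
#' Agglomerative complete-linkage clustering over Euclidean distances, the
#' standard choice for methylation heat maps. Missing values are mean-imputed
#' per probe row before the distance computation. Ties follow the fixed input
#' (item-index) order, so the tree is deterministic for a fixed matrix.
#'
#' @param z Z-score matrix (probes in rows).
#' @param axis Cluster `"columns"` (samples; default) or `"rows"` (probes).
#' @return An [stats::hclust] tree; leaf order via `$order`.
#' @export
hierarchical_cluster <- function(z, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (anyNA(z)) {
    mu <- rowMeans(z, na.rm = TRUE)
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- mu[idx[, 1L]]
  }
  x <- if (axis == "columns") t(z) else z
  if (nrow(x) < 2L) stopf("need at least 2 items to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
}

#' Heatmap of Z-scored probes with two-way clustering
#'
#' Renders the standard methylation heatmap: complete-linkage Euclidean
#' clustering of both probes and samples, columns annotated by group (blue
#' for Control, red for Periodontitis).
#'
#' @param z Z-score matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param file Optional `.png`/`.svg` output path.
#' @return Invisibly, the pheatmap object.
#' @export
plot_heatmap <- function(z, sheet, file = NULL) {
  sheet <- check_sheet_matches(z, sheet)
  if (anyNA(z)) {
    mu <- rowMeans(z, na.rm = TRUE)
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- mu[idx[, 1L]]
  }
  ann <- data.frame(Group = sheet$group, row.names = sheet$sample_id)
  args <- list(mat = z, clustering_method = "complete",
               clustering_distance_rows = "euclidean",
               clustering_distance_cols = "euclidean",
               annotation_col = ann,
               annotation_colors = list(Group = GROUP_COLORS),
               show_rownames = FALSE, show_colnames = FALSE, silent = TRUE)
  ph <- do.call(pheatmap::pheatmap, args)
  if (!is.null(file))
    with_device(file, {
      grid::grid.newpage()
      grid::grid.draw(ph$gtable)
    })
  invisible(ph)
}

#' Dendrogram of samples coloured by group
#'
#' @param hc [stats::hclust] tree over samples.
#' @param sheet Sample sheet (labels coloured blue/red by group).
#' @param file Optional `.png`/`.svg` output path.
#' @export
plot_dendrogram <- function(hc, sheet, file = NULL) {
  draw <- function() {
    graphics::plot(hc, labels = FALSE, hang = -1, main = "Sample clustering",
                   xlab = "", sub = "")
    cols <- GROUP_COLORS[sheet$group[match(hc$labels[hc$order], sheet$sample_id)]]
    graphics::mtext(hc$labels[hc$order], side = 1, at = seq_along(hc$order),
                    col = cols, cex = 0.5, las = 2, line = 0.5)
  }
  if (!is.null(file)) with_device(file, draw()) else draw()
  invisible(hc)
}

#' Principal component analysis of samples
#'
#' PCA of the sample-by-probe matrix with centring only: rows are already
#' Z-scored per probe, so no further scaling is applied. Missing values are
#' mean-imputed per probe first.
#'
#' @param z Z-score matrix (probes in rows).
#' @return List of class `pca_result`: `scores` (samples x components) and
#'   `variance_fraction` (non-increasing, summing to 1 over all components).
#' @export
pca_samples <- function(z) {
  if (ncol(z) < 2L) stopf("need at least 2 samples")
  if (anyNA(z)) {
    mu <- rowMeans(z, na.rm = TRUE)
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- mu[idx[, 1L]]
  }
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, variance_fraction = vf), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d samples: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$variance_fraction[1L],
              100 * x$variance_fraction[min(2L, length(x$variance_fraction))]))
  invisible(x)
}

#' Scatter plot of the first two principal components
#'
#' @param pca A `pca_result` from [pca_samples()].
#' @param sheet Sample sheet (points coloured blue/red by group).
#' @param file Optional `.png`/`.svg` output path.
#' @export
plot_pca <- function(pca, sheet, file = NULL) {
  sc <- pca$scores
  cols <- GROUP_COLORS[sheet$group[match(rownames(sc), sheet$sample_id)]]
  vf <- 100 * pca$variance_fraction
  draw <- function() {
    graphics::plot(sc[, 1L], sc[, 2L], col = cols, pch = 16,
                   xlab = sprintf("PC1 (%.1f%%)", vf[1L]),
                   ylab = sprintf("PC2 (%.1f%%)", vf[2L]))
    graphics::legend("topright", legend = names(GROUP_COLORS),
                     col = GROUP_COLORS, pch = 16, bty = "n")
  }
  if (!is.null(file)) with_device(file, draw()) else draw()
  invisible(pca)
}
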