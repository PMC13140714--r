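# User-facing model interface: dmp_fit() bundles the M transform, per-probe
# linear fits, empirical-Bayes moderation, BH adjustment and B-statistics
# into one classed object.

#' Fit the moderated differential-methylation model
#'
#' The central fitting function: filters probes by missingness, transforms
#' beta to M-values, fits a two-group linear model per CpG, moderates the
#' residual variances by empirical Bayes, and reports moderated t-statistics,
#' BH-adjusted p-values and B-statistics. Group-mean beta values per probe are
#' carried along for downstream directionality classification.
#'
#' @param beta Beta matrix (probes in rows, samples in columns), values in
#'   `[0, 1]` or missing.
#' @param sheet Sample sheet (`sample_id`, `group`, `dataset_id`) covering the
#'   matrix columns.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param epsilon Boundary clamp for the logit2 transform (default `1e-6`).
#' @param max_missing_fraction Probe-level missingness filter applied before
#'   fitting (default 0.8; set `NULL` to skip).
#' @return An object of class `dmpfit` with components `table` (per-probe
#'   statistics: `probe_id, logFC, t, P.Value, adj.P.Val, B, significant,
#'   mean_beta_control, mean_beta_case`), `fits`, `params`, `alpha`,
#'   `n_filtered`, `n_excluded`.
#' @seealso [classify_direction()], [rank_top_genes()], [volcano()]
#' @examples
#' sim <- generate_beta(generate_manifest(cfg <- sim_config(n_probes = 300)), cfg)
#' fit <- dmp_fit(sim$beta, sim$sheet)
#' print(fit)
#' head(coef(fit))
#' @export
dmp_fit <- function(beta, sheet, alpha = 0.05, epsilon = 1e-6,
                    max_missing_fraction = 0.8) {
  validate_beta_matrix(beta)
  validate_sample_sheet(sheet)
  n_filtered <- 0L
  if (!is.null(max_missing_fraction)) {
    beta <- filter_missing(beta, max_missing_fraction)
    n_filtered <- attr(beta, "n_removed")
  }
  m <- beta_to_m(beta, epsilon)
  fits <- fit_linear(m, sheet)
  params <- estimate_moderation(fits)
  mod <- moderated_t(fits, params)
  adj <- adjust_bh(mod$p_value)
  B <- b_statistic(fits, params, mod)
  gm <- group_mean_beta(beta, sheet)
  idx <- match(fits$probe_id, gm$probe_id)
  table <- data.frame(
    probe_id = fits$probe_id,
    logFC = fits$logFC,
    t = mod$t,
    P.Value = mod$p_value,
    adj.P.Val = adj,
    B = B,
    significant = adj < alpha,
    mean_beta_control = gm$mean_beta_control[idx],
    mean_beta_case = gm$mean_beta_case[idx],
    stringsAsFactors = FALSE
  )
  structure(list(table = table, fits = fits, params = params, alpha = alpha,
                 epsilon = epsilon, n_filtered = n_filtered,
                 n_excluded = attr(fits, "n_excluded"),
                 sheet = sheet, call = match.call()),
            class = "dmpfit")
}

#' @export
print.dmpfit <- function(x, ...) {
  cat("Moderated differential methylation fit\n")
  cat(sprintf("  probes tested: %d (filtered by missingness: %d, excluded small-n: %d)\n",
              nrow(x$table), x$n_filtered, x$n_excluded))
  cat(sprintf("  samples: %d Control / %d Periodontitis\n",
              sum(x$sheet$group == "Control"),
              sum(x$sheet$group == "Periodontitis")))
  cat(sprintf("  significant at adj.P < %.3g: %d\n", x$alpha,
              sum(x$table$significant, na.rm = TRUE)))
  print(x$params)
  invisible(x)
}

#' @export
summary.dmpfit <- function(object, ...) {
  tab <- object$table
  dir <- classify_change(tab$mean_beta_control, tab$mean_beta_case)
  sig <- tab$significant %in% TRUE
  out <- list(
    n_tested = nrow(tab),
    n_significant = sum(sig),
    alpha = object$alpha,
    d0 = object$params$d0,
    s0_squared = object$params$s0_squared,
    crossing = table(factor(dir[sig], levels = c("low_to_high", "high_to_low",
                                                 "stable_high", "stable_low")))
  )
  class(out) <- "summary.dmpfit"
  out
}

#' @export
print.summary.dmpfit <- function(x, ...) {
  cat(sprintf("Probes tested: %d; significant (adj.P < %.3g): %d\n",
              x$n_tested, x$alpha, x$n_significant))
  cat(sprintf("Moderation: d0 = %s, s0^2 = %.5g\n",
              if (is.finite(x$d0)) sprintf("%.2f", x$d0) else "Inf", x$s0_squared))
  cat("Significant probes by beta-state change (0.5 boundary):\n")
  print(x$crossing)
  invisible(x)
}

#' @export
coef.dmpfit <- function(object, ...) {
  stats::setNames(object$table$logFC, object$table$probe_id)
}

#' @export
plot.dmpfit <- function(x, ...) {
  volcano(x$table, alpha = x$alpha, ...)
}

#' Write the per-probe statistics table as TSV
#'
#' Columns `probe_id, logFC, t, P.Value, adj.P.Val, B`, mirroring the standard
#' differential-methylation output vocabulary.
#'
#' @param fit A `dmpfit` object or its `table` component.
#' @param path Output file path.
#' @export
write_dmp_tsv <- function(fit, path) {
  tab <- if (inherits(fit, "dmpfit")) fit$table else fit
  utils::write.table(tab[, c("probe_id", "logFC", "t", "P.Value", "adj.P.Val", "B")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
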