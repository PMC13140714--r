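# Per-CpG two-group linear modelling on M-values with empirical-Bayes
# variance moderation, moderated t-statistics, BH adjustment and B-statistics.
#
# The moderation model: per-probe residual variances s2_g with df_g degrees of
# freedom are treated as s2_g | sigma2_g ~ sigma2_g * chisq(df_g)/df_g with an
# inverse-chisquare prior sigma2_g ~ s0^2 * d0 / chisq(d0). The marginal
# distribution of log s2_g is then a shifted log-F, whose mean and variance
# involve digamma/trigamma functions of d0/2 and df_g/2; (d0, s0^2) are
# recovered by a moments match on the log scale.

#' Fit per-probe two-group linear models on M-values
#'
#' Ordinary least squares per CpG with a group-only design: the coefficient of
#' interest is the case-minus-control difference of M-value means (logFC).
#' Missing entries are dropped per probe; probes with fewer than 2 observed
#' samples in either group are excluded (their count is recorded in the
#' `n_excluded` attribute).
#'
#' @param m M-value matrix (probes in rows).
#' @param sheet Sample sheet with a `group` column containing both
#'   `Control` and `Periodontitis`.
#' @return Data frame with columns `probe_id, logFC, s2, df_residual,
#'   stdev_unscaled, n_control, n_case`.
#' @export
fit_linear <- function(m, sheet) {
  validate_sample_sheet(sheet)
  sheet <- check_sheet_matches(m, sheet)
  is_case <- sheet$group == "Periodontitis"
  if (!any(is_case) || all(is_case)) stopf("both groups must be present in the sheet")

  mc <- m[, !is_case, drop = FALSE]
  mk <- m[, is_case, drop = FALSE]
  nc <- rowSums(!is.na(mc))
  nk <- rowSums(!is.na(mk))
  mean_c <- rowMeans(mc, na.rm = TRUE)
  mean_k <- rowMeans(mk, na.rm = TRUE)
  # pooled residual sum of squares about the two group means
  rss <- rowSums((mc - mean_c)^2, na.rm = TRUE) + rowSums((mk - mean_k)^2, na.rm = TRUE)
  df <- nc + nk - 2L

  keep <- nc >= 2L & nk >= 2L
  out <- data.frame(
    probe_id = rownames(m)[keep],
    logFC = (mean_k - mean_c)[keep],
    s2 = (rss / pmax(df, 1L))[keep],
    df_residual = df[keep],
    stdev_unscaled = sqrt(1 / nc + 1 / nk)[keep],
    n_control = nc[keep],
    n_case = nk[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes moderation parameters
#'
#' Recovers the prior degrees of freedom `d0` and prior variance `s0_squared`
#' of the scaled inverse-chisquare prior on per-probe residual variances by
#' the closed-form moments match on log variances: after centring each
#' `log(s2_g)` by its sampling expectation given `df_g`, the excess dispersion
#' beyond the trigamma sampling floor determines `d0`; the mean determines
#' `s0_squared`. When the observed dispersion does not exceed the floor, `d0`
#' is infinite and every variance shrinks fully to `s0_squared`.
#'
#' @param fits Table from [fit_linear()] (uses `s2` and `df_residual`).
#' @return List with `d0`, `s0_squared` (class `moderation_params`).
#' @export
estimate_moderation <- function(fits) {
  ok <- is.finite(fits$s2) & fits$s2 > 0 & fits$df_residual >= 1
  if (sum(ok) < 2L) {
    if (any(is.finite(fits$s2)) && all(fits$s2[is.finite(fits$s2)] == 0))
      stopf("all residual variances are zero; moderation is undefined (check for constant or duplicated samples)")
    stopf("need at least 2 probes with positive finite residual variance")
  }
  s2 <- fits$s2[ok]
  df <- fits$df_residual[ok]
  n <- length(s2)

  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_squared <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # dispersion at or below the sampling floor: fully shared variance
    d0 <- Inf
    s0_squared <- mean(s2)
  }
  structure(list(d0 = d0, s0_squared = s0_squared,
                 b_proportion = 0.01, var_prior_fc = NULL),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("Empirical-Bayes moderation: d0 = %s, s0^2 = %.6g\n",
              if (is.finite(x$d0)) sprintf("%.3f", x$d0) else "Inf",
              x$s0_squared))
  invisible(x)
}

squeeze_var <- function(s2, df, params) {
  if (is.finite(params$d0))
    (params$d0 * params$s0_squared + df * s2) / (params$d0 + df)
  else
    rep(params$s0_squared, length(s2))
}

#' Moderated t-statistics and p-values
#'
#' The per-probe variance is replaced by the posterior (convex) combination
#' `s2_tilde = (d0 s0^2 + df s2) / (d0 + df)`; the moderated t is
#' `logFC / (stdev_unscaled * sqrt(s2_tilde))`, referenced to a t distribution
#' with `d0 + df` degrees of freedom (standard normal when `d0` is infinite).
#'
#' @param fits Table from [fit_linear()].
#' @param params From [estimate_moderation()].
#' @return Data frame `probe_id, logFC, t, p_value, df_total, s2_post`.
#' @export
moderated_t <- function(fits, params) {
  s2_post <- squeeze_var(fits$s2, fits$df_residual, params)
  t <- fits$logFC / (fits$stdev_unscaled * sqrt(s2_post))
  df_total <- fits$df_residual + params$d0
  p <- if (is.finite(params$d0))
    2 * stats::pt(-abs(t), df = df_total)
  else
    2 * stats::pnorm(-abs(t))
  data.frame(probe_id = fits$probe_id, logFC = fits$logFC, t = t,
             p_value = p, df_total = df_total, s2_post = s2_post,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: adjusted p for the i-th order statistic is
#' `min(1, min_{j >= i} m p_(j) / j)`, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  out
}

# var_prior_fc estimation: for the top fraction of probes by |t|, back out the
# coefficient-variance inflation consistent with their t exceeding the null
# quantile at the same tail rank (the framework's t-mixture moment estimator).
estimate_var_prior <- function(tstat, df, stdev_unscaled, proportion = 0.01) {
  ngenes <- length(tstat)
  ntarget <- ceiling(proportion / 2 * ngenes)
  if (ntarget < 1L) return(list(var_prior = 1, ntarget = 0L))
  p <- max(ntarget / ngenes, proportion)
  tstat <- abs(tstat)
  max_df <- max(df)
  i <- df < max_df
  if (any(i)) {
    tstat[i] <- stats::qt(stats::pt(tstat[i], df = df[i], lower.tail = FALSE),
                          df = max_df, lower.tail = FALSE)
  }
  o <- order(tstat, decreasing = TRUE)[seq_len(ntarget)]
  tt <- tstat[o]
  v1 <- stdev_unscaled[o]^2
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(-tt, df = max_df)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = max_df, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((tt[pos] / qtarget)^2 - 1)
  }
  list(var_prior = mean(pmax(v0, 0)), ntarget = ntarget)
}

#' B-statistic (log posterior odds of differential methylation)
#'
#' Closed-form log odds that a probe is differential, given the moderated t,
#' its total degrees of freedom, a prior probability `b_proportion` that a
#' probe is differential, and a prior variance `var_prior_fc` for the
#' coefficient of differential probes (in units of `stdev_unscaled^2`;
#' estimated from the large-|t| tail when not supplied). Even in t and
#' increasing in |t| at fixed degrees of freedom.
#'
#' @param fits Table from [fit_linear()].
#' @param params From [estimate_moderation()]; fields `b_proportion` and
#'   `var_prior_fc` are honoured when set.
#' @param mod Optional precomputed [moderated_t()] table.
#' @return Numeric vector of B-statistics, one per fit row.
#' @export
b_statistic <- function(fits, params, mod = moderated_t(fits, params)) {
  proportion <- if (is.null(params$b_proportion)) 0.01 else params$b_proportion
  stopifnot(proportion > 0, proportion < 1)
  tstat <- mod$t
  df_total <- fits$df_residual + min(params$d0, 1e6)
  v1 <- fits$stdev_unscaled^2
  v0 <- params$var_prior_fc
  if (is.null(v0))
    v0 <- estimate_var_prior(tstat, df_total, fits$stdev_unscaled, proportion)$var_prior
  r <- (v1 + v0) / v1
  t2 <- tstat^2
  kernel <- if (all(is.finite(df_total)))
    (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  else
    t2 * (1 - 1 / r) / 2
  log(proportion / (1 - proportion)) - 0.5 * log(r) + kernel
}
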