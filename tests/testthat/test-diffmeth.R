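test_that("fit_linear reproduces hand-computed fits and antisymmetry", {
  d <- make_beta(control = rbind(c(0, 0), c(1, -1)),
                 case = rbind(c(1, 1), c(2, 0)))
  fits <- fit_linear(d$beta, d$sheet)  # values are already on the M scale here
  expect_equal(fits$logFC, c(1, 1))
  expect_equal(fits$s2, c(0, 2))       # pooled variance of {2,0} and {1,-1} is 2
  expect_equal(fits$df_residual, c(2L, 2L))
  expect_equal(fits$stdev_unscaled, rep(1, 2))

  # swapping group labels negates every logFC
  flipped <- d$sheet
  flipped$group <- ifelse(flipped$group == "Control", "Periodontitis", "Control")
  expect_equal(fit_linear(d$beta, flipped)$logFC, -fits$logFC)

  # probes with < 2 observed per group are excluded with a count
  m <- d$beta
  m[1, 1:2] <- NA
  f2 <- fit_linear(m, d$sheet)
  expect_equal(nrow(f2), 1L)
  expect_equal(attr(f2, "n_excluded"), 1L)

  one_group <- d$sheet; one_group$group <- "Control"
  expect_error(fit_linear(d$beta, one_group), "both groups")
})

test_that("moderation collapses to d0 = Inf under identical variances", {
  fits <- data.frame(probe_id = letters[1:5], logFC = 0, s2 = 1.7,
                     df_residual = 10L, stdev_unscaled = 0.5)
  params <- estimate_moderation(fits)
  expect_false(is.finite(params$d0))
  expect_equal(params$s0_squared, 1.7, tolerance = 1e-9)

  zero <- transform(fits, s2 = 0)
  expect_error(estimate_moderation(zero), "zero")
})

test_that("moderated variances are convex combinations of s2 and s0^2", {
  set.seed(101)
  fits <- data.frame(probe_id = sprintf("p%d", 1:500), logFC = rnorm(500),
                     s2 = rchisq(500, 8) / 8, df_residual = 8L,
                     stdev_unscaled = 0.4)
  params <- estimate_moderation(fits)
  s2_post <- if (is.finite(params$d0))
    (params$d0 * params$s0_squared + fits$df_residual * fits$s2) /
      (params$d0 + fits$df_residual)
  else rep(params$s0_squared, nrow(fits))
  lo <- pmin(fits$s2, params$s0_squared)
  hi <- pmax(fits$s2, params$s0_squared)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
})

test_that("moderation parameter estimates agree with the limma reference", {
  set.seed(7)
  d0 <- 6; s0 <- 0.8; df <- 12; n <- 20000
  sigma2 <- s0 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  fits <- data.frame(probe_id = sprintf("p%d", 1:n), logFC = 0, s2 = s2,
                     df_residual = df, stdev_unscaled = 1)
  params <- estimate_moderation(fits)
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(params$d0, ref$df2, tolerance = 1e-6)
  expect_equal(params$s0_squared, ref$scale, tolerance = 1e-6)
})

test_that("moderated t reduces to known limits", {
  fits <- data.frame(probe_id = c("a", "b"), logFC = c(1, 0),
                     s2 = c(2, 2), df_residual = c(10L, 10L),
                     stdev_unscaled = c(0.5, 0.5))
  # d0 -> 0: ordinary pooled two-sample t
  p0 <- structure(list(d0 = 1e-9, s0_squared = 5), class = "moderation_params")
  mod <- moderated_t(fits, p0)
  expect_equal(mod$t[1], 1 / (0.5 * sqrt(2)), tolerance = 1e-6)
  expect_equal(mod$t[2], 0)
  expect_equal(mod$p_value[2], 1)
  # d0 = Inf: logFC/(stdev_unscaled * s0) referenced to the normal
  pinf <- structure(list(d0 = Inf, s0_squared = 4), class = "moderation_params")
  minf <- moderated_t(fits, pinf)
  expect_equal(minf$t[1], 1 / (0.5 * 2))
  expect_equal(minf$p_value[1], 2 * pnorm(-1))
})

test_that("full moderated pipeline agrees with limma on a shared dataset", {
  cfg <- sim_config(n_probes = 600, n_control = 8, n_case = 8, n_datasets = 1,
                    missing_rate = 0, frac_high_missing_probes = 0, seed = 31)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  m <- beta_to_m(sim$beta)
  fits <- fit_linear(m, sim$sheet)
  params <- estimate_moderation(fits)
  mod <- moderated_t(fits, params)

  design <- cbind(1, sim$sheet$group == "Periodontitis")
  lf <- limma::lmFit(m, design)
  eb <- limma::eBayes(lf)
  expect_equal(mod$logFC, unname(lf$coefficients[, 2]), tolerance = 1e-9)
  expect_equal(params$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(params$s0_squared, eb$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$p_value, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("adjust_bh matches hand computation, brute force and p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.4), 0.4)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(202)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(adjust_bh(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  # NA propagation
  expect_true(is.na(adjust_bh(c(0.1, NA, 0.5))[2]))
})

test_that("B-statistic is even in t, minimal at 0, and positive for large |t|", {
  make_fits <- function(lfc) data.frame(probe_id = sprintf("p%d", seq_along(lfc)),
                                        logFC = lfc, s2 = 1, df_residual = 18L,
                                        stdev_unscaled = 0.3)
  params <- structure(list(d0 = 2, s0_squared = 1, b_proportion = 0.01,
                           var_prior_fc = 0.25), class = "moderation_params")
  lfc <- seq(-3, 3, by = 0.5)
  B <- b_statistic(make_fits(lfc), params)
  expect_equal(B, rev(B), tolerance = 1e-10)              # even in t
  expect_equal(which.min(B), which(lfc == 0))             # minimum at t = 0
  # closed form at |t| = 10, df = 20: log odds exceed 0 despite 1% prior
  f10 <- data.frame(probe_id = "x", logFC = 10 * 0.3 * 1, s2 = 1,
                    df_residual = 18L, stdev_unscaled = 0.3)
  p10 <- structure(list(d0 = 2, s0_squared = 1, b_proportion = 0.01,
                        var_prior_fc = 0.25), class = "moderation_params")
  mod <- moderated_t(f10, p10)
  expect_gt(b_statistic(f10, p10, mod), 0)
})

test_that("dmp_fit assembles a coherent model object", {
  cfg <- sim_config(n_probes = 400, n_control = 6, n_case = 6, n_datasets = 1,
                    seed = 17)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  fit <- dmp_fit(sim$beta, sim$sheet)
  expect_s3_class(fit, "dmpfit")
  tab <- fit$table
  expect_true(all(tab$adj.P.Val >= tab$P.Value - 1e-12))
  expect_true(all(tab$P.Value >= 0 & tab$P.Value <= 1))
  expect_identical(tab$significant, tab$adj.P.Val < fit$alpha)
  expect_named(coef(fit), tab$probe_id)
  s <- summary(fit)
  expect_equal(s$n_significant, sum(tab$significant))
  expect_output(print(fit), "probes tested")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dmp_tsv(fit, tmp)
  back <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(tab))
  expect_named(back, c("probe_id", "logFC", "t", "P.Value", "adj.P.Val", "B"))
})

test_that("planted effects are recovered with controlled FDR", {
  cfg <- sim_config(n_probes = 2000, n_control = 30, n_case = 30,
                    n_datasets = 1, effect_size_m = 2, missing_rate = 0,
                    frac_high_missing_probes = 0, seed = 23)
  sim <- generate_beta(generate_manifest(cfg), cfg)
  fit <- dmp_fit(sim$beta, sim$sheet)
  called <- fit$table$probe_id[fit$table$significant]
  truth <- sim$truth$is_dmp[match(called, sim$truth$probe_id)]
  expect_gt(length(called), 0)
  expect_lte(mean(!truth), 0.10)      # realized FDR
  power <- mean(sim$truth$probe_id[sim$truth$is_dmp] %in% called)
  expect_gt(power, 0.9)
})
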