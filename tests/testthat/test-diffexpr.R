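# build a normalized_matrix directly from a log2 matrix + design
as_nm <- function(lg, design) {
  structure(list(log2_value = lg, probe_id = rownames(lg),
                 is_control = rep(FALSE, nrow(lg)), design = design,
                 provenance = NULL),
            class = "normalized_matrix")
}

two_group_design <- function(n_per = 8, muscle = "LT") {
  data.frame(sample = sprintf("s%d", seq_len(2 * n_per)),
             animal = sprintf("a%d", seq_len(2 * n_per)),
             muscle = muscle,
             stress = rep(c("limited", "stress"), each = n_per),
             diet = rep(rep(c("control", "EP"), each = n_per / 2), 2),
             stringsAsFactors = FALSE)
}

test_that("the stress effect equals the difference of group means", {
  des <- two_group_design(4)
  des$diet <- "control"     # single diet level: plain two-group comparison
  set.seed(10)
  lg <- matrix(rnorm(8 * 6), 6, 8,
               dimnames = list(sprintf("p%d", 1:6), des$sample))
  fit <- fit_probe_models(as_nm(lg, des))
  expected <- rowMeans(lg[, des$stress == "stress"]) -
    rowMeans(lg[, des$stress == "limited"])
  expect_equal(fit$log2_ratio, unname(expected), tolerance = 1e-12)
})

test_that("a constant probe has zero effect and zero residual variance", {
  des <- two_group_design(4)
  lg <- matrix(rnorm(8 * 5), 5, 8,
               dimnames = list(sprintf("p%d", 1:5), des$sample))
  lg[3, ] <- 2.5
  fit <- fit_probe_models(as_nm(lg, des))
  expect_equal(fit$log2_ratio[3], 0, tolerance = 1e-12)
  expect_equal(fit$s2[3], 0, tolerance = 1e-12)
})

test_that("a rank-deficient design names the confounded term", {
  des <- two_group_design(4)
  des$diet <- ifelse(des$stress == "stress", "EP", "control")  # aliased
  lg <- matrix(rnorm(8 * 5), 5, 8,
               dimnames = list(sprintf("p%d", 1:5), des$sample))
  expect_error(fit_probe_models(as_nm(lg, des)), "confounded")
})

test_that("moderated t degenerates to the ordinary t at d0 = 0", {
  des <- two_group_design(8)
  set.seed(11)
  lg <- matrix(rnorm(16 * 50), 50, 16,
               dimnames = list(sprintf("p%d", 1:50), des$sample))
  fit <- fit_probe_models(as_nm(lg, des))
  st <- moderate_t(fit, prior = list(d0 = 0, s0_sq = 1))
  t_ord <- fit$log2_ratio / sqrt(fit$s2 * fit$v_unscaled)
  expect_equal(st$t_mod, t_ord, tolerance = 1e-6)
  p_ord <- 2 * pt(-abs(t_ord), df = fit$df_residual)
  expect_equal(st$p, p_ord, tolerance = 1e-6)
})

test_that("huge d0 pins the posterior variance at the prior", {
  des <- two_group_design(8)
  set.seed(12)
  lg <- matrix(rnorm(16 * 50), 50, 16,
               dimnames = list(sprintf("p%d", 1:50), des$sample))
  fit <- fit_probe_models(as_nm(lg, des))
  s0 <- 0.37
  st <- moderate_t(fit, prior = list(d0 = 1e12, s0_sq = s0))
  t_fixed <- fit$log2_ratio / sqrt(s0 * fit$v_unscaled)
  expect_equal(st$t_mod, t_fixed, tolerance = 1e-6)
})

test_that("the variance prior is recovered from scaled-F distributed s2", {
  set.seed(13)
  d0 <- 8
  s0 <- 0.05
  df <- 28
  s2 <- s0 * d0 / rchisq(5000, d0) * rchisq(5000, df) / df
  pr <- estimate_variance_prior(s2, df)
  expect_equal(pr$d0, d0, tolerance = 0.15)
  expect_equal(pr$s0_sq, s0, tolerance = 0.1)
  expect_error(estimate_variance_prior(rep(0, 100), 28), "zero")
})

test_that("prior estimation and shrinkage agree with limma", {
  skip_if_not_installed("limma")
  set.seed(14)
  s2 <- 0.04 * 6 / rchisq(3000, 6) * rchisq(3000, 20) / 20
  pr <- estimate_variance_prior(s2, 20)
  fd <- limma::fitFDist(s2, df1 = 20)
  expect_equal(pr$d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fd$scale, tolerance = 1e-6)

  fit <- data.frame(probe_id = sprintf("p%d", seq_along(s2)),
                    log2_ratio = rnorm(length(s2), 0, 0.1), s2 = s2,
                    df_residual = 20, v_unscaled = 0.125)
  st <- moderate_t(fit)
  sv <- limma::squeezeVar(s2, 20)
  expect_equal(st$t_mod, fit$log2_ratio / sqrt(sv$var.post * 0.125),
               tolerance = 1e-6)
})

test_that("BH adjustment matches the hand-computed and brute-force oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.42), 0.42)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(15)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(adjust_bh(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("gene calls enforce the 80% rule and sign consistency", {
  map <- data.frame(probe_id = sprintf("p%d", 1:13),
                    gene = c(rep("gA", 5), rep("gB", 5), rep("gC", 3)),
                    stringsAsFactors = FALSE)
  st <- data.frame(
    probe_id = map$probe_id,
    log2_ratio = c(rep(0.9, 5),              # gA: all positive
                   c(0.8, 0.8, 0.8, 0.8, -0.2),  # gB: one negative ratio
                   rep(0.5, 3)),             # gC
    p_adj = c(c(0.01, 0.02, 0.03, 0.05, 0.5),    # gA: 4/5 significant
              c(0.01, 0.02, 0.03, 0.05, 0.5),    # gB: 4/5 significant
              c(0.01, 0.05, 0.5)),               # gC: 2/3 significant
    stringsAsFactors = FALSE)
  calls <- call_genes(st, map)
  gA <- calls[calls$gene == "gA", ]
  expect_true(gA$is_deg)                    # 0.8 >= 0.8 boundary passes
  expect_equal(gA$direction, "up")
  expect_equal(gA$gene_log2_ratio, 0.9)
  expect_false(calls$is_deg[calls$gene == "gB"])  # inconsistent sign
  expect_false(calls$is_deg[calls$gene == "gC"])  # 0.667 < 0.8
  expect_true(is.na(calls$direction[calls$gene == "gB"]))

  bad_map <- rbind(map, data.frame(probe_id = "p1", gene = "gZ"))
  expect_error(call_genes(st, bad_map), "multiple genes")
})

test_that("lowering alpha never enlarges the DEG set", {
  cfg <- small_cfg(seed = 71L)
  e <- generate_expression(cfg)
  nm <- normalize_probes(qc_filter(e$probes))
  fit <- moderate_t(fit_probe_models(nm, muscle = "LT"))
  fit$p_adj <- adjust_bh(fit$p)
  prev <- NULL
  for (a in c(0.20, 0.10, 0.05, 0.01)) {
    degs <- with(call_genes(fit, e$probe_map, alpha = a), gene[is_deg])
    if (!is.null(prev)) expect_true(all(degs %in% prev))
    prev <- degs
  }
})

test_that("null probe-level p-values are approximately uniform", {
  cfg <- null_cfg(seed = 81L, n_probes = 3000L)
  e <- generate_expression(cfg)
  nm <- normalize_probes(qc_filter(e$probes))
  st <- moderate_t(fit_probe_models(nm, muscle = "LT"))
  ks <- suppressWarnings(ks.test(st$p, "punif"))$statistic
  expect_lt(unname(ks), 0.03)
})
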