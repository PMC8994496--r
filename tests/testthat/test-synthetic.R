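test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_control_probes = 2000L, n_probes = 1000L),
               "n_control_probes")
  expect_error(sim_config(n_de_genes = 9000L), "n_de_genes")
  expect_error(sim_config(lfc_range = c(0, 1)), "lfc_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(frac_probe_dropout = 1.2), "frac_probe_dropout")
  expect_error(small_cfg(de_split = c(lt_only = 1L, st_only = 1L, both = 1L)),
               "de_split")
})

test_that("identical seed and config give byte-identical outputs", {
  sim1 <- simulate_dataset(small_cfg(seed = 11L))
  sim2 <- simulate_dataset(small_cfg(seed = 11L))
  expect_identical(sim1, sim2)

  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulation(sim1, d1)
  write_simulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  sim3 <- simulate_dataset(small_cfg(seed = 12L))
  expect_false(identical(sim1$probes$intensity, sim3$probes$intensity))
})

test_that("default configuration reproduces the array dimensions", {
  e <- generate_expression(sim_config(seed = 3L))
  expect_equal(nrow(e$probes$intensity), 10064L)
  expect_equal(sum(e$probes$is_control), 1614L)
  expect_equal(length(unique(e$probe_map$gene)), 4210L)
  expect_equal(nrow(e$design), 64L)  # 32 animals x 2 muscles
  expect_equal(sum(e$design$stress == "stress"), 32L)
})

test_that("without planted effects the stress and limited group means agree", {
  cfg <- small_cfg(n_de_genes = 0L,
                   de_split = c(lt_only = 0L, st_only = 0L, both = 0L),
                   noise_sd = 1e-7, array_effect_sd = 0,
                   frac_probe_dropout = 0, n_qtl_genes = 0L)
  e <- generate_expression(cfg)
  lg <- log2(e$probes$intensity)
  stressed <- e$design$stress == "stress"
  diff <- rowMeans(lg[, stressed]) - rowMeans(lg[, !stressed])
  expect_lt(max(abs(diff)), 1e-6)
})

test_that("a planted log2 effect of +1 is realised in the generated data", {
  # analytic mean of the generative model is exactly 1.0; the Monte-Carlo
  # standard error of the replicate-averaged probe mean difference bounds
  # the tolerated deviation
  diffs <- vapply(1:40, function(s) {
    cfg <- small_cfg(seed = 100L + s, n_de_genes = 1L,
                     de_split = c(lt_only = 1L, st_only = 0L, both = 0L),
                     lfc_range = c(1, 1), noise_sd = 0.2,
                     array_effect_sd = 0, frac_probe_dropout = 0,
                     n_qtl_genes = 1L)
    e <- generate_expression(cfg)
    g <- e$truth$de_genes$gene[1]
    rows <- e$probe_map$probe_id[e$probe_map$gene == g]
    lt <- e$design$muscle == "LT"
    stressed <- e$design$stress == "stress"
    lg <- log2(e$probes$intensity[rows, , drop = FALSE])
    sgn <- sign(e$truth$de_genes$lfc[1])
    sgn * (mean(lg[, lt & stressed]) - mean(lg[, lt & !stressed]))
  }, numeric(1))
  # each replicate mean diff has sd <= noise_sd * sqrt(2/16) ~ 0.071
  se <- 0.2 * sqrt(2 / 16) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.0), 4 * se)
})

test_that("module hits contain the planted targets plus calibrated background", {
  cfg <- small_cfg(seed = 21L, module_background_rate = 0)
  e <- generate_expression(cfg)
  hits <- generate_module_hits(cfg, e$truth)
  for (m in names(e$truth$enriched_modules)) {
    expect_setequal(hits$gene[hits$module == m],
                    e$truth$enriched_modules[[m]]$genes)
  }
  expect_true(all(hits$n_positions >= 1))
  expect_false(anyDuplicated(hits[, c("module", "gene", "promoter_id")]) > 0)

  # background-only module count within the binomial 99.9% band, pooled
  # over seeds
  n_bg <- 0L
  n_trials <- 0L
  for (s in 1:20) {
    cfgb <- small_cfg(seed = 200L + s, module_background_rate = 0.01)
    eb <- generate_expression(cfgb)
    hb <- generate_module_hits(cfgb, eb$truth)
    bg_modules <- setdiff(unique(hb$module), names(eb$truth$enriched_modules))
    n_bg <- n_bg + sum(hb$module %in% bg_modules)
    n_trials <- n_trials + length(setdiff(
      sprintf("M%02d", seq_len(cfgb$n_modules)),
      names(eb$truth$enriched_modules))) * cfgb$n_genes
  }
  lo <- qbinom(5e-4, n_trials, 0.01)
  hi <- qbinom(1 - 5e-4, n_trials, 0.01)
  expect_gte(n_bg, lo)
  expect_lte(n_bg, hi)
})

test_that("empty truth yields background-only module hits", {
  cfg <- small_cfg(seed = 31L, n_de_genes = 0L,
                   de_split = c(lt_only = 0L, st_only = 0L, both = 0L),
                   n_planted_modules = 0L, n_qtl_genes = 0L,
                   module_background_rate = 0)
  e <- generate_expression(cfg)
  hits <- generate_module_hits(cfg, e$truth)
  expect_equal(nrow(hits), 0L)
})

test_that("interaction database wires planted nodes and flawed decoys", {
  cfg <- small_cfg(seed = 41L)
  e <- generate_expression(cfg)
  db_raw <- generate_interaction_db(cfg, e$truth)
  db <- load_interaction_db(db_raw$edges)
  seeds <- e$truth$de_genes$gene
  for (r in e$truth$planted_regulators) {
    re <- db$edges[db$edges$source == r &
                     db$edges$relation_type == "Regulation" &
                     db$edges$target %in% seeds, ]
    expect_gte(length(unique(re$target)), 2L)
    expect_gte(max(re$n_references), 3L)
    expect_gte(db$degree[[r]], 6L)
  }
  for (t in e$truth$planted_targets) {
    te <- db$edges[db$edges$target == t &
                     db$edges$relation_type == "Expression" &
                     db$edges$source %in% seeds, ]
    expect_gte(length(unique(te$source)), 2L)
    expect_gte(max(te$n_references), 3L)
    expect_gte(db$degree[[t]], 6L)
  }
  # planted regulators/targets are never DEGs
  expect_length(intersect(e$truth$planted_regulators, seeds), 0)
  expect_length(intersect(e$truth$planted_targets, seeds), 0)
  # every decoy is rejected by the default filters
  nx <- extract_network(db, seeds, profile = "muscle")
  expect_length(intersect(db_raw$decoys$node, c(nx$regulators, nx$targets)), 0)
})

test_that("planted QTL-spanning genes are contained and others are not", {
  cfg <- small_cfg(seed = 51L)
  e <- generate_expression(cfg)
  geo <- generate_loci_and_qtls(cfg, e$truth)
  hits <- suppressWarnings(map_genes_to_qtls(geo$loci, geo$qtls))
  expect_true(all(e$truth$qtl_spanning_genes %in% hits$gene))
  expect_setequal(unique(hits$gene), e$truth$qtl_spanning_genes)
})

test_that("annotation generator plants a recoverable term", {
  cfg <- small_cfg(seed = 61L)
  e <- generate_expression(cfg)
  ann <- generate_annotations(cfg, e$truth)
  universe <- unique(e$probe_map$gene)
  res <- enrich(e$truth$de_genes$gene, universe, ann, fdr_cut = 0.08)
  expect_true("T0001" %in% res$term_id[res$significant])

  cfg0 <- small_cfg(seed = 62L, n_terms = 0L)
  e0 <- generate_expression(cfg0)
  expect_equal(nrow(generate_annotations(cfg0, e0$truth)), 0L)
})
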