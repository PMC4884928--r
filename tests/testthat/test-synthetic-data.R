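test_that("sim_config rejects invalid study designs", {
  expect_error(sim_config(n_controls = 1), "n_controls")
  expect_error(sim_config(days = c(1, 3, 5)), "days")
  expect_error(sim_config(days = c(0, 3, 1)), "days")
  expect_error(sim_config(ppi_edge_prob = 1.5), "ppi_edge_prob")
  expect_error(sim_config(fingerprint_bits = 4), "fingerprint_bits")
  expect_error(
    sim_config(category_fractions = c(C1 = 0.5, C2 = 0.1, C3 = 0.1,
                                      C4 = 0.1, C5 = 0.1,
                                      background = 0.2)),
    "sum to 1")
  expect_error(sim_config(ppi_nodes = 4, planted_path_length = 3),
               "planted_path_length")
})

test_that("expression dataset has the study layout and matching labels", {
  cfg <- sim_config(n_genes = 1000, n_drugs = 16, n_controls = 14,
                    seed = 7)
  g <- gen_expression_dataset(cfg)
  expect_equal(ncol(g$dataset$values), 14 + 16 * 3)
  expect_equal(nrow(g$dataset$values), 1000)
  expect_setequal(unique(g$dataset$meta$day), c(0, 1, 3, 5))
  # realized category fractions within multinomial sampling error (4 SE)
  frac <- table(g$truth$categories) / 1000
  for (lab in names(cfg$category_fractions)) {
    p <- cfg$category_fractions[[lab]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(frac[[lab]] - p), 4 * se + 1e-12)
  }
})

test_that("same seed gives bit-identical synthetic outputs", {
  cfg <- small_cfg(seed = 42)
  a <- gen_expression_dataset(cfg)
  b <- gen_expression_dataset(cfg)
  expect_identical(a, b)
  expect_identical(gen_screen_table(cfg, 40, 4), gen_screen_table(cfg, 40, 4))
  expect_identical(gen_ppi_network(cfg), gen_ppi_network(cfg))
  expect_identical(gen_fingerprints(cfg), gen_fingerprints(cfg))
})

test_that("planted C4 genes satisfy the 3-sigma final-day rule, background does not", {
  hits <- sapply(1:5, function(sd) {
    cfg <- small_cfg(seed = sd)
    g <- gen_expression_dataset(cfg)
    c4 <- names(g$truth$categories)[g$truth$categories == "C4"]
    final <- max(g$dataset$meta$day)
    x <- day_matrix(g$dataset, final)[c4, , drop = FALSE]
    base <- rowMeans(g$dataset$values[c4,
      control_columns(g$dataset), drop = FALSE])
    # every drug beyond 3 true noise SDs
    mean(rowSums(abs(x - base) > 3 * cfg$noise_sd) == ncol(x))
  })
  expect_gte(mean(hits), 0.95)

  # all-background config: few (gene, drug) pairs exceed 3 sigma at day 5
  cfg <- sim_config(n_genes = 500, n_drugs = 6, ppi_nodes = 50,
                    category_fractions = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0,
                                           C5 = 0, background = 1),
                    undetected_fraction = 0, seed = 11)
  g <- gen_expression_dataset(cfg)
  x <- day_matrix(g$dataset, 5)
  base <- rowMeans(g$dataset$values[, control_columns(g$dataset)])
  expect_lt(mean(abs(x - base) > 3 * cfg$noise_sd), 0.05)
})

test_that("screen generator plants recoverable effective drugs and a basal level", {
  cfg <- small_cfg(seed = 5)
  s <- gen_screen_table(cfg, n_library = 100, n_effective = 5)
  z <- compute_zscores(s$table)
  expect_setequal(select_effective(z), s$truth$effective_drugs)

  s0 <- gen_screen_table(cfg, n_library = 50, n_effective = 0)
  expect_length(select_effective(compute_zscores(s0$table)), 0)

  # non-effective drugs sit near the 25% basal differentiation level
  meds <- sapply(1:5, function(sd) {
    s <- gen_screen_table(small_cfg(seed = sd), n_library = 100,
                          n_effective = 5)
    bg <- !(s$table$drug %in% s$truth$effective_drugs)
    median(s$table$pct_differentiated[bg])
  })
  expect_true(all(meds >= 20 & meds <= 30))
})

test_that("ppi generator plants a backbone that is the shortest route", {
  cfg <- sim_config(n_genes = 100, n_drugs = 4, ppi_nodes = 50,
                    ppi_edge_prob = 0, planted_path_length = 3, seed = 2)
  p <- gen_ppi_network(cfg)
  expect_setequal(edge_key(p$network$edges$nodeA, p$network$edges$nodeB),
                  p$truth$backbone_edges)
  g <- igraph::graph_from_data_frame(p$network$edges[, 1:2],
                                     directed = FALSE,
                                     vertices = p$network$nodes)
  expect_equal(
    as.numeric(igraph::distances(g, p$truth$entry_node,
                                 p$truth$deg_nodes)), 3)

  # low background density: backbone still shortest in nearly all seeds
  ok <- sapply(1:100, function(sd) {
    cfg <- sim_config(n_genes = 100, n_drugs = 4, ppi_nodes = 200,
                      ppi_edge_prob = 0.02, planted_path_length = 3,
                      seed = sd)
    p <- gen_ppi_network(cfg)
    keep <- p$network$edges$confidence >= 0.8
    g <- igraph::graph_from_data_frame(p$network$edges[keep, 1:2],
                                       directed = FALSE,
                                       vertices = p$network$nodes)
    igraph::distances(g, p$truth$entry_node, p$truth$deg_nodes)[1, 1] ==
      cfg$planted_path_length
  })
  expect_gte(mean(ok), 0.9)
})

test_that("drug-target generator shares the entry node and exercises the filter", {
  cfg <- small_cfg(seed = 3)
  p <- gen_ppi_network(cfg)
  tg <- gen_drug_targets(cfg, p$network, p$truth,
                         drug_ids = c("drugA", "drugB"))
  ft <- filter_targets(tg$table)
  expect_gt(jaccard(ft$target[ft$drug == "drugA"],
                    ft$target[ft$drug == "drugB"]), 0)

  tg2 <- gen_drug_targets(small_cfg(seed = 4, low_conf_fraction = 1,
                                    targets_per_drug = 3),
                          p$network, truth = NULL,
                          drug_ids = c("drugA", "drugB"))
  expect_equal(nrow(filter_targets(tg2$table)), 0)
})

test_that("fingerprint groups hit their target Tanimoto score", {
  cfg <- small_cfg(seed = 6)
  fp1 <- gen_fingerprints(cfg, drug_ids = c("a", "b"),
                          groups = list(c("a", "b")), ts_target = 1)
  expect_equal(tanimoto(fp1["a", ], fp1["b", ]), 1)

  # independent fingerprints: E[TS] ~ density/(2 - density) ~ 0.05
  cfg2 <- sim_config(n_genes = 10, n_drugs = 40, ppi_nodes = 20,
                     fingerprint_bits = 1024, fingerprint_density = 0.1,
                     seed = 8)
  fp2 <- gen_fingerprints(cfg2)
  ts <- tanimoto_matrix(fp2)
  expect_lt(abs(mean(ts[upper.tri(ts)]) - 0.05), 0.01)

  fp3 <- gen_fingerprints(cfg, drug_ids = c("a", "b", "c"),
                          groups = list(c("a", "b")), ts_target = 0.9)
  realized <- tanimoto(fp3["a", ], fp3["b", ])
  expect_gte(realized, 0.85)
  expect_lte(realized, 0.95)
})
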