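test_that("control model fits per-gene mean and sample SD", {
  ctrl <- matrix(c(1, 2, 3,
                   5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  data <- toy_dataset(ctrl, list(drugA = matrix(0, 2, 3,
                                                dimnames = list(c("gA", "gB"),
                                                                NULL))))
  m <- fit_control_model(data)
  expect_equal(unname(m$mean), c(2, 5))
  expect_equal(unname(m$sd), c(1, 0))
  expect_equal(m$n_replicates, 3)

  one_rep <- toy_dataset(ctrl[, 1, drop = FALSE],
                         list(drugA = matrix(0, 2, 3,
                                             dimnames = list(c("gA", "gB"),
                                                             NULL))))
  expect_error(fit_control_model(one_rep), ">= 2")
})

test_that("fitted sigma is consistent with the generating noise SD", {
  s <- 0.2
  ctrl <- toy_controls(10000, 14, sd = s, seed = 99)
  data <- toy_dataset(ctrl, list(drugA = ctrl[, 1:3]))
  m <- fit_control_model(data)
  expect_gt(median(m$sd), 0.9 * s)
  expect_lt(median(m$sd), 1.1 * s)
})

test_that("detection filter keeps genes detected on at least one day", {
  ctrl <- toy_controls(3, 3, seed = 1)
  det <- matrix(0.5, 3, 6, dimnames = list(rownames(ctrl), NULL))
  det[1, 5] <- 0.01        # detected once, mid course -> kept
  det[2, ] <- 0.01         # always detected -> kept
  data <- toy_dataset(ctrl, list(drugA = ctrl[, 1:3] * 0 + 8),
                      detection = det)
  kept <- filter_detected(data)
  expect_setequal(rownames(kept$values), c("g001", "g002"))

  # planted undetected fraction is recovered by the filter
  cfg <- small_cfg(seed = 12, undetected_fraction = 0.1)
  g <- gen_expression_dataset(cfg)
  kept <- filter_detected(g$dataset)
  dropped <- setdiff(rownames(g$dataset$values), rownames(kept$values))
  expect_setequal(dropped, g$truth$undetected)
  expect_equal(length(dropped) / cfg$n_genes, 0.1, tolerance = 0.02)
})

test_that("3-sigma differential rule uses a strict inequality", {
  model <- structure(list(mean = c(gA = 10), sd = c(gA = 0.5),
                          n_replicates = 14), class = "control_model")
  expect_false(is_differential(c(gA = 10), model))
  expect_true(is_differential(c(gA = 12), model))        # |2| > 1.5
  expect_false(is_differential(c(gA = 11.5), model))     # exactly 3 sigma
  zero <- structure(list(mean = c(gA = 10), sd = c(gA = 0),
                         n_replicates = 14), class = "control_model")
  expect_error(is_differential(c(gA = 10), zero), "gA")
})

test_that("pairwise differences cover all unordered drug pairs", {
  ctrl <- toy_controls(2, 3, seed = 2)
  per_drug <- list(drugA = matrix(c(5, 1, 5, 1, 5, 1), 2),
                   drugB = matrix(c(8, 1, 8, 1, 8, 1), 2))
  data <- toy_dataset(ctrl, per_drug)
  d <- pairwise_diffs(data, 1)
  expect_equal(ncol(d), 1)
  expect_equal(unname(d["g001", 1]), 3)
  expect_equal(unname(d["g002", 1]), 0)
  expect_error(pairwise_diffs(data, 7), "day 7")

  cfg <- sim_config(n_genes = 20, n_drugs = 16, ppi_nodes = 30, seed = 3)
  g <- gen_expression_dataset(cfg)
  expect_equal(ncol(pairwise_diffs(g$dataset, 1)), 120)
})

test_that("divergent-convergent flag follows the 3-sigma window rule", {
  genes <- c("gA", "gB")
  model <- structure(list(mean = c(gA = 0, gB = 0),
                          sd = c(gA = 1, gB = 1), n_replicates = 14),
                     class = "control_model")
  mk <- function(day, vals) {
    m <- matrix(vals, 2, 1, dimnames = list(genes, "p"))
    structure(m, day = day, drugs = c("a", "b"),
              class = c("pairwise_diffs", "matrix", "array"))
  }
  # gA: mean d = 5 sigma at day 3, 0.5 sigma at day 5 -> flagged
  # gB: constant zero differences -> not flagged
  flags <- classify_divergent_convergent(
    list(mk(1, c(0.2, 0)), mk(3, c(5, 0)), mk(5, c(0.5, 0))), model)
  expect_true(flags[["gA"]])
  expect_false(flags[["gB"]])

  zero_model <- structure(list(mean = c(gA = 0, gB = 0),
                               sd = c(gA = 1, gB = 0), n_replicates = 14),
                          class = "control_model")
  expect_warning(
    f2 <- classify_divergent_convergent(
      list(mk(1, c(0.2, 0)), mk(3, c(5, 0)), mk(5, c(0.5, 0))),
      zero_model),
    "excluded")
  expect_true(is.na(f2[["gB"]]))
  expect_equal(attr(f2, "n_excluded"), 1)
})

test_that("category labels are exhaustive, exclusive, and order-invariant", {
  cfg <- small_cfg(seed = 21)
  g <- gen_expression_dataset(cfg)
  data <- filter_detected(g$dataset)
  model <- fit_control_model(data)
  cats <- assign_categories(data, model)
  expect_false(anyNA(cats$label))
  expect_true(all(cats$label %in% c("C1", "C2", "C3", "C4", "C5",
                                    "background")))
  # gene order must not matter
  perm <- sample(nrow(data$values))
  cats2 <- assign_categories(subset_genes(data, perm), model)
  expect_identical(cats2$label[match(cats$gene, cats2$gene)], cats$label)
})

test_that("planted C1 and C4 genes land in their categories", {
  cfg <- small_cfg(seed = 31)
  g <- gen_expression_dataset(cfg)
  data <- filter_detected(g$dataset)
  model <- fit_control_model(data)
  cats <- assign_categories(data, model)
  truth <- g$truth$categories[cats$gene]
  expect_gt(mean(cats$label[truth == "C4"] == "C4"), 0.9)
  expect_gt(mean(cats$label[truth == "C1"] == "C1"), 0.9)
  # background genes may leak into the C5 catch-all at the false-positive
  # rate of the 3-sigma rule, but essentially never into C1/C3/C4
  expect_lt(mean(cats$label[truth == "background"] %in%
                   c("C1", "C3", "C4")), 0.01)
})

test_that("modified Pearson matches its closed forms and bounds", {
  a <- c(1, 3, 5, 7)
  m <- c(2, 2, 4, 8)
  expect_equal(modified_pearson(a, a, m), 1)
  b <- m - (a - m)
  expect_equal(modified_pearson(a, b, m), -1)
  # means equal to each sample's cross-gene mean -> standard Pearson
  set.seed(5)
  x <- rnorm(50)
  y <- rnorm(50)
  expect_equal(modified_pearson(x, y, rep(mean(x), 50), rep(mean(y), 50)),
               cor(x, y))
  expect_error(modified_pearson(a, a, a), "degenerate")
  # property: bounded in [-1, 1] for random non-degenerate inputs
  for (i in 1:50) {
    set.seed(i)
    r <- modified_pearson(rnorm(20), rnorm(20), rnorm(20), rnorm(20))
    expect_gte(r, -1)
    expect_lte(r, 1)
  }
})

test_that("dispersion is computed per day over all drug pairs", {
  ctrl <- toy_controls(5, 4, baseline = 0, sd = 0.1, seed = 7)
  set.seed(8)
  course <- matrix(rnorm(15), 5, 3,
                   dimnames = list(rownames(ctrl), NULL))
  data <- toy_dataset(ctrl, list(drugA = course, drugB = course))
  model <- fit_control_model(data)
  disp <- dispersion_by_day(data, model)
  expect_equal(nrow(disp), 3)                 # one pair per day
  expect_equal(disp$r, rep(1, 3))             # identical drugs correlate at 1
})

test_that("planted divergence puts the correlation minimum at day 3", {
  cfg <- small_cfg(seed = 41)
  g <- gen_expression_dataset(cfg)
  data <- filter_detected(g$dataset)
  model <- fit_control_model(data)
  disp <- dispersion_by_day(data, model)
  mr <- tapply(disp$r, disp$day, mean)
  expect_equal(names(which.min(mr)), "3")
})

test_that("gene-subsampled dispersion is deterministic and sized correctly", {
  cfg <- small_cfg(seed = 51)
  g <- gen_expression_dataset(cfg)
  model <- fit_control_model(g$dataset)
  a <- subsample_dispersion(g$dataset, model, n_genes = 50, n_reps = 3,
                            seed = 9)
  b <- subsample_dispersion(g$dataset, model, n_genes = 50, n_reps = 3,
                            seed = 9)
  expect_identical(a, b)
  one <- subsample_dispersion(g$dataset, model, n_genes = 50, n_reps = 1,
                              seed = 9)
  expect_equal(nrow(one), 3 * choose(cfg$n_drugs, 2))
  expect_error(subsample_dispersion(g$dataset, model, n_genes = 1e6),
               "exceeds")
})

test_that("PCA projection maps duplicates together and separates clusters", {
  ctrl <- toy_controls(20, 4, baseline = 0, sd = 0.05, seed = 10)
  set.seed(11)
  shifted <- matrix(rnorm(60, 5, 0.05), 20, 3,
                    dimnames = list(rownames(ctrl), NULL))
  data <- toy_dataset(ctrl, list(drugA = shifted, drugB = shifted))
  p <- pca_project(data, n_components = 2)
  expect_lte(sum(p$explained_variance), 1)
  # duplicated samples (drugA vs drugB) share coordinates
  a <- p$scores[p$scores$drug == "drugA", c("PC1", "PC2")]
  b <- p$scores[p$scores$drug == "drugB", c("PC1", "PC2")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)),
               tolerance = 1e-8)
  # PC1 separates controls from the shifted cluster
  pc1_ctrl <- p$scores$PC1[p$scores$drug == "control"]
  pc1_trt <- p$scores$PC1[p$scores$drug != "control"]
  expect_true(max(pc1_ctrl) < min(pc1_trt) ||
                min(pc1_ctrl) > max(pc1_trt))
})
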