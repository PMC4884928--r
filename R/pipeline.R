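#' End-to-end pipeline configuration
#'
#' Collects every stage threshold and the global seed. Per-stage seeds are
#' derived deterministically from the global seed, so adding a stage never
#' perturbs the randomness of earlier stages; re-running with the same
#' configuration reproduces identical artifacts.
#'
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param n_library screen library size.
#' @param diff_z,tox_z screen selection thresholds.
#' @param alpha detection p-value cutoff.
#' @param k SD multiplier of the differential rule.
#' @param majority_fraction drug quorum for the N and T category flags.
#' @param fold DEG fold-change threshold for CAP-Net.
#' @param min_conf confidence threshold for targets and network edges.
#' @param min_support minimum drug support of a CAP-Net edge.
#' @param n_perm shared-target permutation draws.
#' @param n_null CAP-Net null-model draws.
#' @param subsample_genes,subsample_reps gene-subsampling dispersion
#'   settings.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       n_library = 100L,
                       diff_z = 1.8, tox_z = -1,
                       alpha = 0.05, k = 3, majority_fraction = 0.5,
                       fold = 1.5, min_conf = 0.8, min_support = 2,
                       n_perm = 10000L, n_null = 10000L,
                       subsample_genes = 500L, subsample_reps = 100L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, k > 0, fold >= 1,
            majority_fraction >= 0, majority_fraction < 1,
            min_conf >= 0, min_conf <= 1, min_support >= 1,
            n_perm >= 1, n_null >= 1)
  structure(list(sim = sim, n_library = as.integer(n_library),
                 diff_z = diff_z, tox_z = tox_z, alpha = alpha, k = k,
                 majority_fraction = majority_fraction, fold = fold,
                 min_conf = min_conf, min_support = as.integer(min_support),
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 subsample_genes = as.integer(subsample_genes),
                 subsample_reps = as.integer(subsample_reps),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate -> screen -> trajectory -> similarity -> CAP-Net -> report.
#' Generates all synthetic inputs with planted ground truth, calls screen
#' hits, classifies genes into trajectory categories, computes dispersion
#' and PCA summaries, drug similarity statistics, and the CAP-Net with
#' empirical p-values and planted-backbone recovery. Each stage's failure
#' is surfaced with the stage name. All artifacts are plain-text files
#' under `out_dir`; a JSON manifest records the configuration and seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and
#'   `artifacts`, the written file paths.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sim <- cfg$sim
  sim$seed <- derive_seed(cfg$seed, 100L)
  art <- character(0)

  ## --- simulate -------------------------------------------------------
  gen <- stage("simulate", {
    expr <- gen_expression_dataset(sim)
    screen <- gen_screen_table(sim, n_library = cfg$n_library,
                               n_effective = sim$n_drugs)
    planted_deg <- names(expr$truth$categories)[
      expr$truth$categories == "C4"]
    ppi_nodes <- sample_ppi_nodes(expr, sim, planted_deg)
    ppi <- gen_ppi_network(sim, node_ids = ppi_nodes,
                           deg_candidates = intersect(ppi_nodes,
                                                      planted_deg))
    targets <- gen_drug_targets(sim, ppi$network, ppi$truth)
    fps <- gen_fingerprints(sim)
    list(expr = expr, screen = screen, ppi = ppi, targets = targets,
         fps = fps)
  })
  art["expr"] <- write_expression_dataset(gen$expr$dataset, out_dir)[["values"]]
  art["screen"] <- write_screen_table(gen$screen$table,
                                      file.path(out_dir, "screen.csv"))
  art["ppi"] <- write_ppi_network(gen$ppi$network,
                                  file.path(out_dir, "ppi.tsv"))
  art["targets"] <- write_drug_targets(gen$targets$table,
                                       file.path(out_dir, "targets.tsv"))
  art["fps"] <- write_fingerprints(gen$fps,
                                   file.path(out_dir, "fingerprints.tsv"))
  truth <- structure(c(unclass(gen$expr$truth), unclass(gen$screen$truth),
                       unclass(gen$ppi$truth), unclass(gen$targets$truth)),
                     class = "ground_truth")
  art["truth"] <- write_ground_truth(truth,
                                     file.path(out_dir, "ground_truth.json"))

  ## --- screen ---------------------------------------------------------
  hits <- stage("screen", {
    calls <- compute_zscores(gen$screen$table)
    sel <- select_effective(calls, cfg$diff_z, cfg$tox_z)
    calls$effective <- calls$drug %in% sel
    list(calls = calls[order(-calls$z_diff), ], selected = sel)
  })
  art["hits"] <- file.path(out_dir, "hits.tsv")
  utils::write.table(hits$calls, art["hits"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- trajectory -----------------------------------------------------
  traj <- stage("trajectory", {
    filtered <- filter_detected(gen$expr$dataset, cfg$alpha)
    model <- fit_control_model(filtered)
    cats <- assign_categories(filtered, model, k = cfg$k,
                              majority_fraction = cfg$majority_fraction)
    disp <- dispersion_by_day(filtered, model)
    sub <- subsample_dispersion(filtered, model,
                                n_genes = cfg$subsample_genes,
                                n_reps = cfg$subsample_reps,
                                seed = derive_seed(cfg$seed, 101L))
    pca <- pca_project(filtered)
    list(filtered = filtered, model = model, categories = cats,
         dispersion = disp, subsampled = sub, pca = pca)
  })
  art["categories"] <- file.path(out_dir, "categories.tsv")
  utils::write.table(traj$categories, art["categories"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art["dispersion"] <- file.path(out_dir, "dispersion.tsv")
  utils::write.table(traj$dispersion, art["dispersion"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art["pca"] <- file.path(out_dir, "pca.tsv")
  utils::write.table(traj$pca$scores, art["pca"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- similarity -----------------------------------------------------
  simi <- stage("similarity", {
    drugs <- treated_drugs(gen$expr$dataset)
    top_dose <- max(gen$screen$table$dose)
    eff_rows <- gen$screen$table$drug %in% drugs &
      gen$screen$table$dose == top_dose
    eff <- gen$screen$table$pct_differentiated[eff_rows]
    names(eff) <- gen$screen$table$drug[eff_rows]
    ts <- tanimoto_matrix(gen$fps)
    sets <- target_sets(gen$targets$table, drugs, cfg$min_conf)
    deg_sets <- lapply(drugs, function(d)
      select_degs(traj$filtered, d, max(treated_days(traj$filtered)),
                  fold = cfg$fold, model = traj$model))
    names(deg_sets) <- drugs
    idx <- utils::combn(length(drugs), 2)
    a <- drugs[idx[1, ]]
    b <- drugs[idx[2, ]]
    pairs <- data.frame(drug_a = a, drug_b = b,
                        ts = ts[cbind(a, b)],
                        shared_targets = mapply(function(x, y)
                          length(intersect(sets[[x]], sets[[y]])), a, b),
                        ji_targets = mapply(function(x, y)
                          if (length(union(sets[[x]], sets[[y]])) == 0) NA
                          else jaccard(sets[[x]], sets[[y]]), a, b),
                        ji_degs = mapply(function(x, y)
                          jaccard(deg_sets[[x]], deg_sets[[y]]), a, b),
                        eff_sim = efficiency_similarity(eff[a], eff[b]),
                        stringsAsFactors = FALSE)
    pairs$p_shared <- mapply(function(x, y)
      shared_target_pvalue(x, y, gen$targets$table,
                           unique(gen$screen$table$drug),
                           min_conf = cfg$min_conf, n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, 102L))$p_value,
      a, b)
    cors <- similarity_correlations(pairs, c("ts", "ji_degs"))
    list(pairs = pairs, correlations = cors, efficiencies = eff)
  })
  art["similarity"] <- file.path(out_dir, "similarity_pairs.tsv")
  utils::write.table(simi$pairs, art["similarity"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- capnet ---------------------------------------------------------
  capres <- stage("capnet", {
    drugs <- treated_drugs(gen$expr$dataset)
    final_day <- max(treated_days(traj$filtered))
    spnets <- lapply(drugs, function(d) {
      tg <- gen$targets$table$target[gen$targets$table$drug == d &
                                       gen$targets$table$confidence >=
                                       cfg$min_conf]
      dg <- select_degs(traj$filtered, d, final_day, fold = cfg$fold,
                        model = traj$model)
      build_spnet(gen$ppi$network, tg, dg, min_conf = cfg$min_conf,
                  drug = d)
    })
    change <- rowMeans(day_matrix(traj$filtered, final_day)) -
      traj$model$mean[rownames(traj$filtered$values)]
    cap <- intersect_spnets(spnets, min_support = cfg$min_support,
                            expr_change = change)
    cap <- capnet_pvalues(cap, gen$ppi$network, min_conf = cfg$min_conf,
                          n_null = cfg$n_null,
                          seed = derive_seed(cfg$seed, 103L))
    rec <- recover_planted(cap, truth)
    list(spnets = spnets, capnet = cap, recovery = rec)
  })
  cap_paths <- write_capnet(capres$capnet, out_dir)
  art["capnet_edges"] <- cap_paths[["edges"]]
  art["capnet_nodes"] <- cap_paths[["nodes"]]

  ## --- report ---------------------------------------------------------
  stage("report", {
    manifest <- list(package = "exitpaths",
                     version = as.character(utils::packageVersion("exitpaths")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     seed = cfg$seed,
                     config = unclass(cfg)[setdiff(names(cfg), "sim")],
                     sim_config = unclass(cfg$sim))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(pipeline_summary(cfg, hits, traj, simi, capres),
               file.path(out_dir, "summary.md"))
  })
  art["manifest"] <- file.path(out_dir, "manifest.json")
  art["summary"] <- file.path(out_dir, "summary.md")

  invisible(list(generated = gen, truth = truth, hits = hits,
                 trajectory = traj, similarity = simi, capnet = capres,
                 artifacts = art))
}

# PPI node universe for the integrated pipeline: planted C4 genes (so the
# backbone endpoint is a genuine strong DEG) plus random other genes.
sample_ppi_nodes <- function(expr, sim, planted_deg) {
  genes <- names(expr$truth$categories)
  n <- min(sim$ppi_nodes, length(genes))
  with_seed(derive_seed(sim$seed, 6L), {
    need_deg <- intersect(genes, planted_deg)
    take_deg <- utils::head(need_deg, max(1, min(length(need_deg),
                                                 round(n / 10))))
    rest <- sample(setdiff(genes, take_deg), n - length(take_deg))
    sort(c(take_deg, rest))
  })
}

pipeline_summary <- function(cfg, hits, traj, simi, capres) {
  counts <- table(factor(traj$categories$label,
                         levels = c("C1", "C2", "C3", "C4", "C5",
                                    "background")))
  mean_r <- stats::aggregate(r ~ day, traj$dispersion, mean)
  c("# Pipeline summary",
    "",
    sprintf("- screen hits (Z_diff > %g, Z_tox > %g): %d [%s]",
            cfg$diff_z, cfg$tox_z, length(hits$selected),
            paste(hits$selected, collapse = ", ")),
    sprintf("- genes after detection filter: %d",
            nrow(traj$filtered$values)),
    sprintf("- category counts: %s",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", ")),
    sprintf("- mean pairwise modified-Pearson r by day: %s",
            paste(sprintf("day %g: %.3f", mean_r$day, mean_r$r),
                  collapse = "; ")),
    sprintf("- similarity correlations vs Eff-Sim: TS %.3f, shared-DEG JI %.3f",
            simi$correlations[["ts"]], simi$correlations[["ji_degs"]]),
    sprintf("- CAP-Net: %d edges, backbone recall %.2f, precision %.2f",
            nrow(capres$capnet$edges), capres$recovery$recall,
            capres$recovery$precision))
}
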