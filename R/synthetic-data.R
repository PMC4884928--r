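#' Synthetic pipeline inputs with planted ground truth
#'
#' The generators in this module emulate every input of the analysis —
#' expression time courses with untreated replicates, a differentiation
#' screen table, a protein-interaction network, a drug-target table and
#' chemical fingerprints — with known planted structure, so each downstream
#' stage can be validated against ground truth.
#'
#' `gen_expression_dataset()` plants the five trajectory categories:
#' \describe{
#'   \item{C1}{drug-specific excursions at the intermediate days (magnitude
#'     at least `effect_sd_multiplier` noise SDs, sign and size varying per
#'     drug, maximal at the middle of the course) that collapse back to
#'     baseline by the final day: divergent-convergent without net change.}
#'   \item{C2}{a concordant transient excursion, identical across drugs,
#'     returning to baseline: transient but not divergent.}
#'   \item{C3}{drug-specific intermediate excursions converging to a common
#'     shifted final level: divergent-convergent with net change.}
#'   \item{C4}{a concordant monotone ramp to a common shifted final level:
#'     net change without divergence.}
#'   \item{C5}{a shift in a single drug only, too rare to reach any
#'     majority quorum.}
#' }
#' Background genes stay within replicate noise. A configurable fraction of
#' background genes is planted as "undetected" (detection p-values uniform
#' on \[0.05, 1\] everywhere); all other genes receive detection p-values
#' below 0.05.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `dataset` (an [expr_dataset()]) and `truth`
#'   (a `ground_truth` list with `categories`, a gene -> label vector, and
#'   `undetected`, the planted undetected gene ids).
#' @export
gen_expression_dataset <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
    td <- cfg$days[-1]                     # treated days; day 0 = controls
    K <- length(td)
    early <- if (K > 1) td[-K] else numeric(0)
    final <- td[K]
    e <- cfg$effect_sd_multiplier * cfg$noise_sd

    labels <- sample(names(cfg$category_fractions), cfg$n_genes,
                     replace = TRUE, prob = cfg$category_fractions)
    names(labels) <- genes
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    # Per-gene common shift (C2/C3/C4/C5) and per-(gene,drug) specific
    # magnitudes (C1/C3), both >= the configured effect size.
    common <- sample(c(-1, 1), cfg$n_genes, replace = TRUE) *
      stats::runif(cfg$n_genes, e, e + 2 * cfg$noise_sd)
    spec_mag <- matrix(sample(c(-1, 1), cfg$n_genes * cfg$n_drugs,
                              replace = TRUE) *
                         stats::runif(cfg$n_genes * cfg$n_drugs,
                                      e, e + 2 * cfg$noise_sd),
                       nrow = cfg$n_genes)
    c5_drug <- sample.int(cfg$n_drugs, cfg$n_genes, replace = TRUE)

    # Ramp weights: divergent classes peak at the last intermediate day;
    # C4 ramps monotonically to the final level.
    w_early <- if (K > 1) seq_len(K - 1) / (K - 1) else numeric(0)
    w_ramp <- seq_len(K) / K

    displacement <- function(drug_idx, day_idx) {
      day <- td[day_idx]
      disp <- numeric(cfg$n_genes)
      is_early <- day_idx < K
      we <- if (is_early) w_early[day_idx] else 0
      i <- labels == "C1"
      disp[i] <- if (is_early) we * spec_mag[i, drug_idx] else 0
      i <- labels == "C3"
      disp[i] <- if (is_early) we * spec_mag[i, drug_idx] else common[i]
      i <- labels == "C4"
      disp[i] <- w_ramp[day_idx] * common[i]
      i <- labels == "C2"
      disp[i] <- if (is_early) common[i] else 0
      i <- labels == "C5" & c5_drug == drug_idx
      disp[i] <- common[i]
      disp
    }

    n_samp <- cfg$n_controls + cfg$n_drugs * K
    values <- matrix(NA_real_, cfg$n_genes, n_samp)
    rownames(values) <- genes
    ctrl_ids <- sprintf("CTRL_%02d", seq_len(cfg$n_controls))
    for (j in seq_len(cfg$n_controls))
      values[, j] <- baseline + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)

    trt_ids <- character(cfg$n_drugs * K)
    meta_drug <- character(n_samp)
    meta_day <- numeric(n_samp)
    meta_drug[seq_len(cfg$n_controls)] <- "control"
    meta_day[seq_len(cfg$n_controls)] <- 0
    col <- cfg$n_controls
    for (d in seq_len(cfg$n_drugs)) {
      for (k in seq_len(K)) {
        col <- col + 1
        values[, col] <- baseline + displacement(d, k) +
          stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
        trt_ids[col - cfg$n_controls] <- sprintf("%s_D%g", drugs[d], td[k])
        meta_drug[col] <- drugs[d]
        meta_day[col] <- td[k]
      }
    }
    colnames(values) <- c(ctrl_ids, trt_ids)

    detection <- matrix(stats::runif(length(values), 0, 0.01),
                        nrow = cfg$n_genes, dimnames = dimnames(values))
    n_und <- round(cfg$undetected_fraction * cfg$n_genes)
    bg <- genes[labels == "background"]
    if (n_und > length(bg))
      stop("undetected_fraction exceeds the background category fraction")
    undetected <- if (n_und > 0) sample(bg, n_und) else character(0)
    if (n_und > 0)
      detection[undetected, ] <- stats::runif(n_und * n_samp, 0.05, 1)

    meta <- data.frame(sample_id = colnames(values),
                       drug = meta_drug,
                       dose = ifelse(meta_drug == "control", NA_real_, 10),
                       day = meta_day,
                       stringsAsFactors = FALSE)
    truth <- structure(list(categories = labels,
                            undetected = sort(undetected)),
                       class = "ground_truth")
    list(dataset = expr_dataset(values, detection, meta), truth = truth)
  })
}

#' Synthetic differentiation screen table
#'
#' Emulates a high-content screen of a drug library at four doses: percent
#' lipid-positive (differentiated) cells and live-cell count per drug and
#' dose. Non-effective drugs fluctuate around a basal spontaneous
#' differentiation level (about 25% by default, dose-independent); planted
#' effective drugs reach a high differentiation percentage at the top dose
#' without losing viability; optional toxic decoys also differentiate but
#' kill most cells at the top dose.
#'
#' @param cfg a [sim_config()].
#' @param n_library library size.
#' @param n_effective number of planted effective drugs (<= n_library).
#' @param n_toxic number of toxic decoys.
#' @param doses dose series; the last entry is the top (reference) dose.
#' @param basal_pct basal spontaneous differentiation percentage.
#' @param effective_ids optional ids for the planted effective drugs
#'   (defaults to `drug01..`, matching [gen_expression_dataset()]).
#' @return list with `table` (data.frame: drug, dose, pct_differentiated,
#'   live_cells) and `truth` (`effective_drugs`, `toxic_drugs`).
#' @export
gen_screen_table <- function(cfg, n_library = 100L,
                             n_effective = cfg$n_drugs,
                             n_toxic = 0L,
                             doses = c(0.08, 0.4, 2, 10),
                             basal_pct = 25,
                             effective_ids = NULL) {
  validate_sim_config(cfg)
  if (n_effective > n_library)
    stop("'n_effective' cannot exceed 'n_library'")
  if (n_effective + n_toxic > n_library)
    stop("'n_effective' + 'n_toxic' cannot exceed 'n_library'")
  with_seed(derive_seed(cfg$seed, 2L), {
    if (is.null(effective_ids))
      effective_ids <- sprintf("drug%02d", seq_len(n_effective))
    stopifnot(length(effective_ids) == n_effective)
    n_rest <- n_library - n_effective
    rest_ids <- sprintf("lib%04d", seq_len(n_rest))
    toxic_ids <- if (n_toxic > 0) rest_ids[seq_len(n_toxic)] else character(0)
    all_ids <- c(effective_ids, rest_ids)

    K <- length(doses)
    rows <- vector("list", n_library)
    for (i in seq_along(all_ids)) {
      id <- all_ids[i]
      if (id %in% effective_ids) {
        top <- stats::runif(1, 70, 90)
        pct <- basal_pct + (top - basal_pct) * (seq_len(K) / K) +
          stats::rnorm(K, 0, 2)
        live <- stats::rnorm(K, 520, 20)
      } else if (id %in% toxic_ids) {
        top <- stats::runif(1, 40, 90)
        pct <- basal_pct + (top - basal_pct) * (seq_len(K) / K) +
          stats::rnorm(K, 0, 2)
        live <- 500 - (500 - 150) * (seq_len(K) / K) + stats::rnorm(K, 0, 20)
      } else {
        # basal spontaneous differentiation: bounded fluctuation around
        # basal_pct, so an unplanted drug can never cross the hit threshold
        pct <- stats::runif(K, basal_pct - 7, basal_pct + 7)
        live <- stats::rnorm(K, 500, 40)
      }
      rows[[i]] <- data.frame(drug = id, dose = doses,
                              pct_differentiated = pmin(pmax(pct, 0), 100),
                              live_cells = round(pmax(live, 0)),
                              stringsAsFactors = FALSE)
    }
    truth <- structure(list(effective_drugs = sort(effective_ids),
                            toxic_drugs = sort(toxic_ids)),
                       class = "ground_truth")
    list(table = do.call(rbind, rows), truth = truth)
  })
}

#' Synthetic protein-interaction network with a planted backbone
#'
#' Generates a STRING-like undirected edge list: an Erdos-Renyi (or
#' Barabasi-Albert) background with confidence weights uniform on \[0, 1\],
#' plus a planted backbone chain of `planted_path_length` edges at
#' confidence 1.0 connecting a designated drug-target entry node to a
#' designated DEG node. At low background density the backbone is, with
#' high probability, the unique shortest route between its endpoints.
#'
#' @param cfg a [sim_config()].
#' @param node_ids optional node names (length `ppi_nodes`); defaults to
#'   `P001..`. When wiring the network to an expression dataset, pass gene
#'   ids here and planted DEG gene ids as `deg_candidates`.
#' @param deg_candidates optional subset of `node_ids` from which the
#'   backbone DEG endpoint is drawn.
#' @return list with `network` (class `ppi_network`: `edges` data.frame
#'   nodeA/nodeB/confidence plus `nodes`) and `truth` (`backbone_edges`
#'   canonical keys, `backbone_nodes`, `entry_node`, `deg_nodes`).
#' @export
gen_ppi_network <- function(cfg, node_ids = NULL, deg_candidates = NULL) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- cfg$ppi_nodes
    if (is.null(node_ids)) node_ids <- sprintf("P%03d", seq_len(n))
    if (length(node_ids) != n)
      stop("'node_ids' must have length ppi_nodes")
    L <- cfg$planted_path_length

    # Backbone: entry target node -> L-1 intermediates -> DEG node.
    deg_pool <- if (is.null(deg_candidates)) node_ids else
      intersect(node_ids, deg_candidates)
    if (length(deg_pool) == 0)
      stop("no backbone DEG candidate maps onto the node set")
    deg_node <- sample(deg_pool, 1)
    others <- sample(setdiff(node_ids, deg_node), L)
    chain <- c(others, deg_node)        # L+1 nodes, entry first
    entry <- chain[1]
    bb_a <- chain[-length(chain)]
    bb_b <- chain[-1]
    bb_keys <- edge_key(bb_a, bb_b)

    if (cfg$ppi_model == "erdos_renyi") {
      g <- igraph::sample_gnp(n, cfg$ppi_edge_prob, directed = FALSE)
    } else {
      g <- igraph::sample_pa(n, m = max(1, round(cfg$ppi_edge_prob * n / 2)),
                             directed = FALSE)
    }
    ends <- igraph::as_edgelist(g, names = FALSE)
    bg <- data.frame(nodeA = node_ids[ends[, 1]], nodeB = node_ids[ends[, 2]],
                     stringsAsFactors = FALSE)
    bg <- bg[!edge_key(bg$nodeA, bg$nodeB) %in% bb_keys, , drop = FALSE]
    bg$confidence <- stats::runif(nrow(bg))
    edges <- rbind(data.frame(nodeA = bb_a, nodeB = bb_b, confidence = 1,
                              stringsAsFactors = FALSE), bg)
    network <- structure(list(edges = edges, nodes = node_ids),
                         class = "ppi_network")
    truth <- structure(list(backbone_edges = bb_keys,
                            backbone_nodes = chain,
                            entry_node = entry,
                            deg_nodes = deg_node),
                       class = "ground_truth")
    list(network = network, truth = truth)
  })
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Synthetic drug-target table
#'
#' STITCH-like rows (drug, target, confidence). Planted effective drugs all
#' receive the backbone entry node as a high-confidence target; remaining
#' targets are random network nodes whose confidence falls below 0.8 for a
#' configurable fraction of rows, so the confidence filter is exercised.
#'
#' @param cfg a [sim_config()].
#' @param network a `ppi_network` (for the node universe).
#' @param truth the ground truth from [gen_ppi_network()] (for the entry
#'   node); pass `NULL` to assign all targets at random.
#' @param drug_ids drugs to assign targets to; default `drug01..n_drugs`.
#' @param effective_ids drugs sharing the backbone entry node; default all
#'   of `drug_ids`.
#' @return list with `table` (data.frame drug/target/confidence) and
#'   `truth` (`targets`: named list drug -> planted target nodes).
#' @export
gen_drug_targets <- function(cfg, network, truth = NULL,
                             drug_ids = sprintf("drug%02d",
                                                seq_len(cfg$n_drugs)),
                             effective_ids = drug_ids) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 4L), {
    entry <- if (!is.null(truth)) truth$entry_node else NULL
    avoid <- if (!is.null(truth)) truth$backbone_nodes else character(0)
    pool <- setdiff(network$nodes, avoid)
    rows <- vector("list", length(drug_ids))
    targets <- vector("list", length(drug_ids))
    names(targets) <- drug_ids
    for (i in seq_along(drug_ids)) {
      id <- drug_ids[i]
      tg <- character(0)
      cf <- numeric(0)
      if (!is.null(entry) && id %in% effective_ids) {
        tg <- entry
        cf <- stats::runif(1, 0.8, 1)
      }
      n_extra <- cfg$targets_per_drug - length(tg)
      if (n_extra > 0) {
        extra <- sample(pool, n_extra)
        low <- stats::runif(n_extra) < cfg$low_conf_fraction
        cf_extra <- ifelse(low, stats::runif(n_extra, 0.4, 0.8 - 1e-6),
                           stats::runif(n_extra, 0.8, 1))
        tg <- c(tg, extra)
        cf <- c(cf, cf_extra)
      }
      rows[[i]] <- data.frame(drug = id, target = tg, confidence = cf,
                              stringsAsFactors = FALSE)
      targets[[id]] <- tg
    }
    list(table = do.call(rbind, rows),
         truth = structure(list(targets = targets), class = "ground_truth"))
  })
}

#' Synthetic chemical fingerprints
#'
#' Random binary fingerprints of fixed length and density. Drugs placed in
#' the same similarity group share a common core of set bits sized so that
#' their pairwise Tanimoto score is close to `ts_target`: if both drugs
#' carry k set bits of which a fraction s is shared, TS = s / (2 - s), so
#' the core fraction is s = 2 t / (1 + t).
#'
#' @param cfg a [sim_config()].
#' @param drug_ids drugs to fingerprint.
#' @param groups optional list of character vectors (drug ids) forming
#'   similarity groups.
#' @param ts_target target within-group Tanimoto score.
#' @return integer 0/1 matrix, drugs in rows, class `fingerprint_set`.
#' @export
gen_fingerprints <- function(cfg,
                             drug_ids = sprintf("drug%02d",
                                                seq_len(cfg$n_drugs)),
                             groups = NULL, ts_target = 0.9) {
  validate_sim_config(cfg)
  if (ts_target <= 0 || ts_target > 1)
    stop("'ts_target' must lie in (0, 1]")
  with_seed(derive_seed(cfg$seed, 5L), {
    B <- cfg$fingerprint_bits
    k <- max(1L, round(cfg$fingerprint_density * B))
    fp <- matrix(0L, length(drug_ids), B,
                 dimnames = list(drug_ids, NULL))
    grouped <- unlist(groups)
    if (anyDuplicated(grouped))
      stop("similarity groups must be disjoint")
    for (id in setdiff(drug_ids, grouped))
      fp[id, sample.int(B, k)] <- 1L
    s <- 2 * ts_target / (1 + ts_target)
    core_size <- min(k, round(s * k))
    for (grp in groups) {
      core <- sample.int(B, core_size)
      for (id in grp) {
        extra <- sample(setdiff(seq_len(B), core), k - core_size)
        fp[id, c(core, extra)] <- 1L
      }
    }
    structure(fp, class = c("fingerprint_set", class(fp)))
  })
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprint set:", nrow(x), "drugs x", ncol(x), "bits; mean density",
      signif(mean(x), 3), "\n")
  invisible(x)
}
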