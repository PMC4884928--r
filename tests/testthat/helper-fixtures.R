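# Shared fixture builders; everything is generated in code at test time.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_genes = 300, n_drugs = 6, ppi_nodes = 100, seed = seed, ...)
}

# Hand-built expression dataset: `control` is a genes x replicates matrix,
# `per_drug` a named list drug -> genes x days matrix (columns = days).
toy_dataset <- function(control, per_drug, days = c(1, 3, 5),
                        detection = NULL) {
  genes <- rownames(control)
  stopifnot(!is.null(genes))
  mats <- lapply(names(per_drug), function(d) {
    m <- per_drug[[d]]
    colnames(m) <- sprintf("%s_D%g", d, days)
    m
  })
  values <- do.call(cbind, c(list(control), mats))
  meta <- data.frame(
    sample_id = colnames(values),
    drug = c(rep("control", ncol(control)),
             rep(names(per_drug), each = length(days))),
    dose = c(rep(NA_real_, ncol(control)),
             rep(10, length(per_drug) * length(days))),
    day = c(rep(0, ncol(control)), rep(days, length(per_drug))),
    stringsAsFactors = FALSE)
  if (is.null(detection))
    detection <- matrix(0.01, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  expr_dataset(values, detection, meta)
}

# Control matrix with given per-gene noise around a baseline.
toy_controls <- function(n_genes, n_reps, baseline = 8, sd = 0.2,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_reps, baseline, sd), n_genes, n_reps)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("CTRL_%02d", seq_len(n_reps)))
  m
}

# Small interaction network from an explicit edge list.
toy_network <- function(edges, confidence = 1) {
  df <- data.frame(nodeA = edges[, 1], nodeB = edges[, 2],
                   confidence = rep_len(confidence, nrow(edges)),
                   stringsAsFactors = FALSE)
  structure(list(edges = df,
                 nodes = sort(unique(c(df$nodeA, df$nodeB)))),
            class = "ppi_network")
}

# Brute-force SPNet oracle: union of edges over igraph's explicit
# enumeration of all shortest paths between every (target, deg) pair.
brute_force_spnet <- function(net, targets, degs, min_conf = 0.8) {
  keep <- net$edges$confidence >= min_conf
  g <- igraph::graph_from_data_frame(
    net$edges[keep, c("nodeA", "nodeB")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  keys <- character(0)
  for (t in intersect(targets, net$nodes)) {
    for (gd in intersect(degs, net$nodes)) {
      if (t == gd) next
      suppressWarnings(
        paths <- igraph::all_shortest_paths(g, from = t, to = gd)$vpaths)
      for (p in paths) {
        nm <- names(p)
        if (length(nm) < 2) next
        keys <- c(keys, edge_key(nm[-length(nm)], nm[-1]))
      }
    }
  }
  sort(unique(keys))
}
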