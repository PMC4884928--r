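#' Select differentially expressed genes by fold change
#'
#' DEGs feeding the CAP-Net analysis: genes at least `fold`-fold up- or
#' down-regulated between a drug-treated sample and the control mean. On
#' log2 data this is `|x - mean^0| >= log2(fold)` (inclusive boundary); on
#' linear data the ratio to the control mean is tested directly.
#'
#' @param data an [expr_dataset()].
#' @param drug,day the treated sample.
#' @param fold fold-change threshold (default 1.5).
#' @param model optional [fit_control_model()]; fitted from `data`'s
#'   controls when `NULL`.
#' @param linear set `TRUE` when `data` is on linear scale.
#' @return character vector of DEG ids.
#' @export
select_degs <- function(data, drug, day, fold = 1.5, model = NULL,
                        linear = FALSE) {
  if (fold < 1) stop("'fold' must be >= 1")
  if (is.null(model)) model <- fit_control_model(data)
  x <- data$values[, sample_column(data, drug, day)]
  m0 <- model$mean[rownames(data$values)]
  if (linear) {
    if (any(m0 <= 0))
      stop("control mean <= 0 on linear scale: fold change undefined")
    ratio <- x / m0
    hit <- ratio >= fold | ratio <= 1 / fold
  } else {
    hit <- abs(x - m0) >= log2(fold)
  }
  rownames(data$values)[hit]
}

# Confidence-filtered igraph from a ppi_network; unweighted, undirected.
filtered_graph <- function(net, min_conf = 0.8) {
  keep <- net$edges$confidence >= min_conf
  el <- net$edges[keep, c("nodeA", "nodeB"), drop = FALSE]
  if (any(el$nodeA == el$nodeB)) stop("network contains self-loops")
  if (anyDuplicated(edge_key(el$nodeA, el$nodeB)))
    stop("network contains duplicate undirected edges")
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Build a per-drug shortest-path network (SPNet)
#'
#' For one drug, the union of the edges lying on *any* shortest path
#' (hop-count metric, all equal-length ties included) between each of the
#' drug's targets and each of its differentially expressed genes, computed
#' on the confidence-filtered interaction network. An edge (u, v) lies on
#' a shortest path from t to g iff
#' `d(t,u) + 1 + d(v,g) = d(t,g)` in either orientation — the edge set of
#' the BFS shortest-path DAG, equivalent to enumerating all tied paths but
#' immune to their combinatorial number. Targets or DEGs absent from the
#' network are reported, not fatal; disconnected pairs are recorded as
#' unreachable.
#'
#' @param net a `ppi_network`.
#' @param targets character vector of the drug's target nodes (non-empty).
#' @param degs character vector of the drug's DEG nodes (non-empty).
#' @param min_conf edge-confidence threshold (edges below it are removed
#'   before path finding; confidences never weight the paths).
#' @param drug optional drug id carried in the result.
#' @return object of class `spnet`: `edges` (data.frame nodeA/nodeB),
#'   `edge_keys`, `provenance` (per edge, the target-DEG pairs whose
#'   shortest paths traverse it), `pairs` (per target-DEG pair, hop
#'   distance and reachability), `unmapped_targets`, `unmapped_degs`.
#' @export
build_spnet <- function(net, targets, degs, min_conf = 0.8, drug = NA) {
  if (length(targets) == 0) stop("empty target set")
  if (length(degs) == 0) stop("empty DEG set")
  targets <- unique(targets)
  degs <- unique(degs)
  g <- filtered_graph(net, min_conf)
  nodes <- igraph::V(g)$name
  unmapped_t <- setdiff(targets, nodes)
  unmapped_g <- setdiff(degs, nodes)
  tm <- setdiff(targets, unmapped_t)
  gm <- setdiff(degs, unmapped_g)

  el <- igraph::as_edgelist(g, names = TRUE)
  keys <- if (nrow(el)) edge_key(el[, 1], el[, 2]) else character(0)
  prov <- list()
  pair_rows <- list()
  if (length(tm) > 0 && length(gm) > 0 && nrow(el) > 0) {
    dt <- igraph::distances(g, v = tm)
    dg <- igraph::distances(g, v = gm)
    for (t in tm) {
      for (gd in gm) {
        dist_tg <- dt[t, gd]
        if (!is.finite(dist_tg) || t == gd) {
          pair_rows[[length(pair_rows) + 1]] <-
            data.frame(target = t, deg = gd, distance = dist_tg,
                       reachable = is.finite(dist_tg),
                       stringsAsFactors = FALSE)
          next
        }
        on <- (dt[t, el[, 1]] + 1 + dg[gd, el[, 2]] == dist_tg) |
          (dt[t, el[, 2]] + 1 + dg[gd, el[, 1]] == dist_tg)
        for (key in keys[on]) {
          prov[[key]] <- rbind(prov[[key]],
                               data.frame(target = t, deg = gd,
                                          distance = dist_tg,
                                          stringsAsFactors = FALSE))
        }
        pair_rows[[length(pair_rows) + 1]] <-
          data.frame(target = t, deg = gd, distance = dist_tg,
                     reachable = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  edge_keys <- if (length(prov)) sort(names(prov)) else character(0)
  structure(list(drug = drug,
                 edges = as.data.frame(edge_key_split(edge_keys),
                                       stringsAsFactors = FALSE),
                 edge_keys = edge_keys,
                 provenance = prov[edge_keys],
                 pairs = if (length(pair_rows))
                   do.call(rbind, pair_rows) else
                     data.frame(target = character(0), deg = character(0),
                                distance = numeric(0),
                                reachable = logical(0)),
                 targets = targets, degs = degs,
                 unmapped_targets = unmapped_t,
                 unmapped_degs = unmapped_g,
                 min_conf = min_conf),
            class = "spnet")
}

#' @export
print.spnet <- function(x, ...) {
  cat("SPNet", if (!is.na(x$drug)) paste0("(", x$drug, ")") else "", ":",
      length(x$edge_keys), "edges from", nrow(x$pairs),
      "target-DEG pairs (", sum(!x$pairs$reachable), "unreachable )\n")
  invisible(x)
}

#' Intersect SPNets into the CAP-Net
#'
#' The Commonly Affected Paths Network: every edge appearing in the
#' SPNets of at least `min_support` different drugs (default 2), with its
#' drug-support count. Setting `min_support` to the number of drugs gives
#' the strict all-drug intersection.
#'
#' @param spnets list of [build_spnet()] results (>= 2).
#' @param min_support minimum number of supporting drugs per edge.
#' @param expr_change optional named vector (node -> mean expression
#'   change) attached to the node annotations.
#' @return object of class `capnet`: `edges` (nodeA, nodeB, support),
#'   `edge_keys`, `support`, `nodes` (node, is_target_of,
#'   mean_expression_change), `drugs`, `min_support`, `min_conf`.
#' @export
intersect_spnets <- function(spnets, min_support = 2, expr_change = NULL) {
  if (length(spnets) < 2)
    stop("need >= 2 SPNets to intersect")
  if (!all(vapply(spnets, inherits, logical(1), "spnet")))
    stop("'spnets' must be a list of spnet objects")
  mc <- unique(vapply(spnets, function(s) s$min_conf, numeric(1)))
  if (length(mc) > 1)
    stop("SPNets were built at different confidence thresholds")
  drugs <- vapply(seq_along(spnets), function(i) {
    d <- spnets[[i]]$drug
    if (is.na(d)) paste0("drug", i) else as.character(d)
  }, character(1))
  tab <- table(unlist(lapply(spnets, function(s) unique(s$edge_keys))))
  keep <- sort(names(tab)[tab >= min_support])
  support <- as.integer(tab[keep])
  names(support) <- keep
  em <- edge_key_split(keep)
  edges <- data.frame(em, support = support, row.names = NULL,
                      stringsAsFactors = FALSE)
  cap_nodes <- sort(unique(c(em[, 1], em[, 2])))
  is_target_of <- vapply(cap_nodes, function(nd) {
    who <- drugs[vapply(spnets, function(s) nd %in% s$targets, logical(1))]
    paste(who, collapse = ",")
  }, character(1))
  nodes <- data.frame(node = cap_nodes, is_target_of = is_target_of,
                      mean_expression_change =
                        if (is.null(expr_change)) NA_real_
                        else unname(expr_change[cap_nodes]),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, edge_keys = keep, support = support,
                 nodes = nodes, drugs = drugs,
                 min_support = min_support, min_conf = mc),
            class = "capnet")
}

#' @export
print.capnet <- function(x, ...) {
  cat("CAP-Net:", nrow(x$edges), "edges over", nrow(x$nodes),
      "nodes (support >=", x$min_support, "of", length(x$drugs),
      "drugs)\n")
  if ("p_value" %in% names(x$edges))
    cat("  empirical p-values in [",
        signif(min(x$edges$p_value), 3), ",",
        signif(max(x$edges$p_value), 3), "]\n")
  invisible(x)
}

#' Empirical p-values for CAP-Net edges
#'
#' Null model for edge significance: how often does a CAP-Net edge occur
#' in the all-shortest-paths edge set of a uniformly random connected node
#' pair of the filtered network? `n_null` pairs are drawn (disconnected
#' pairs are resampled); for each CAP edge,
#' `p = (1 + draws containing the edge) / (n_null + 1)`. Deterministic
#' under `seed`.
#'
#' @param cap a [intersect_spnets()] result.
#' @param net the `ppi_network` the SPNets were built on.
#' @param min_conf confidence threshold (defaults to the one recorded in
#'   `cap`).
#' @param n_null number of random pair draws (default 10000).
#' @param seed RNG seed.
#' @return `cap` with a `p_value` column added to `edges`.
#' @export
capnet_pvalues <- function(cap, net, min_conf = cap$min_conf,
                           n_null = 10000, seed = 1) {
  g <- filtered_graph(net, min_conf)
  n <- igraph::vcount(g)
  if (n < 2) stop("network must have >= 2 nodes")
  if (nrow(cap$edges) == 0) {
    cap$edges$p_value <- numeric(0)
    return(cap)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  net_keys <- edge_key(el[, 1], el[, 2])
  missing <- setdiff(cap$edge_keys, net_keys)
  if (length(missing) > 0)
    stop("CAP-Net edge(s) absent from the filtered network: ",
         paste(utils::head(missing, 5), collapse = ", "))
  D <- igraph::distances(g)
  nodes <- igraph::V(g)$name
  dimnames(D) <- list(nodes, nodes)
  if (!any(is.finite(D[upper.tri(D)])))
    stop("network has no connected node pair")
  ai <- match(cap$edges$nodeA, nodes)
  bi <- match(cap$edges$nodeB, nodes)
  counts <- integer(nrow(cap$edges))
  with_seed(seed, {
    done <- 0
    while (done < n_null) {
      todo <- n_null - done
      s <- sample.int(n, todo, replace = TRUE)
      t <- sample.int(n, todo, replace = TRUE)
      okp <- s != t & is.finite(D[cbind(s, t)])
      s <- s[okp]
      t <- t[okp]
      for (q in seq_along(s)) {
        dst <- D[s[q], t[q]]
        on <- (D[s[q], ai] + 1 + D[bi, t[q]] == dst) |
          (D[s[q], bi] + 1 + D[ai, t[q]] == dst)
        counts <- counts + on
      }
      done <- done + length(s)
    }
  })
  cap$edges$p_value <- (1 + counts) / (n_null + 1)
  cap$n_null <- n_null
  cap
}

#' Precision and recall against a planted backbone
#'
#' Compares the CAP-Net edge set with the planted backbone edges of a
#' synthetic network. An empty CAP-Net yields recall 0 and precision
#' reported as 0 with the `empty_capnet` flag set.
#'
#' @param cap a `capnet`.
#' @param truth ground truth with a `backbone_edges` element (canonical
#'   edge keys).
#' @return list: `precision`, `recall`, `tp`, `n_capnet`, `n_planted`,
#'   `empty_capnet`.
#' @export
recover_planted <- function(cap, truth) {
  planted <- truth$backbone_edges
  if (is.null(planted)) stop("ground truth lacks 'backbone_edges'")
  tp <- length(intersect(cap$edge_keys, planted))
  empty <- length(cap$edge_keys) == 0
  list(precision = if (empty) 0 else tp / length(cap$edge_keys),
       recall = tp / length(planted),
       tp = tp, n_capnet = length(cap$edge_keys),
       n_planted = length(planted), empty_capnet = empty)
}

#' Write CAP-Net artifacts
#'
#' Writes the edge table (nodeA, nodeB, support, p_value when present),
#' the node table, a GraphML file and a SIF file.
#'
#' @param cap a `capnet`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return written paths, invisibly.
#' @export
write_capnet <- function(cap, dir, prefix = "capnet") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  p_graphml <- file.path(dir, paste0(prefix, ".graphml"))
  p_sif <- file.path(dir, paste0(prefix, ".sif"))
  utils::write.table(cap$edges, p_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cap$nodes, p_nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(cap$edges, directed = FALSE)
  igraph::write_graph(g, p_graphml, format = "graphml")
  writeLines(paste(cap$edges$nodeA, "pp", cap$edges$nodeB), p_sif)
  invisible(c(edges = p_edges, nodes = p_nodes, graphml = p_graphml,
              sif = p_sif))
}
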