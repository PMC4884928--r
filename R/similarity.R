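#' Tanimoto score between two fingerprints
#'
#' Chemical 2D-fingerprint similarity `TS = XY / (X + Y - XY)`, where X
#' and Y are the counts of set bits in each fingerprint and XY the count
#' of bits set in their bitwise AND. TS lies in \[0, 1\]; scores of 0.9 or
#' more indicate close structural similarity.
#'
#' @param fp_a,fp_b equal-length 0/1 (or logical) bit vectors.
#' @return the Tanimoto score.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprints must share one length")
  x <- sum(fp_a != 0)
  y <- sum(fp_b != 0)
  if (x == 0 && y == 0)
    stop("both fingerprints are empty: Tanimoto score undefined (0/0)")
  xy <- sum(fp_a != 0 & fp_b != 0)
  xy / (x + y - xy)
}

#' Pairwise Tanimoto matrix
#'
#' @param fps a `fingerprint_set` matrix (drugs x bits).
#' @return symmetric matrix of Tanimoto scores with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  m <- (unclass(fps) != 0) * 1L
  counts <- rowSums(m)
  if (any(counts == 0))
    stop("empty fingerprint(s): ",
         paste(rownames(m)[counts == 0], collapse = ", "))
  xy <- tcrossprod(m)
  ts <- xy / (outer(counts, counts, "+") - xy)
  dimnames(ts) <- list(rownames(fps), rownames(fps))
  ts
}

#' Efficiency similarity
#'
#' `Eff-Sim(a, b) = 100 - |E(a) - E(b)|` for two differentiation
#' efficiencies in percent; 100 means identical efficacy.
#'
#' @param e_a,e_b efficiencies in \[0, 100\] (vectorized).
#' @return similarity score(s) in \[0, 100\].
#' @export
efficiency_similarity <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 100 | e_b < 0 | e_b > 100))
    stop("efficiencies must lie in [0, 100]")
  100 - abs(e_a - e_b)
}

#' Jaccard index of two sets
#'
#' `JI = |A intersect B| / |A union B|`.
#'
#' @param set_a,set_b vectors interpreted as sets; not both empty.
#' @return the Jaccard index in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0)
    stop("both sets are empty: Jaccard index undefined")
  length(intersect(set_a, set_b)) / u
}

#' Filter drug-target rows by confidence
#'
#' Keeps high-confidence drug-target pairs: `confidence >= min_conf`
#' (inclusive; 0.8 by default, limiting false-positive target
#' assignments).
#'
#' @param table data.frame with columns `drug`, `target`, `confidence`.
#' @param min_conf inclusive confidence threshold.
#' @return the filtered table (possibly zero rows, schema preserved).
#' @export
filter_targets <- function(table, min_conf = 0.8) {
  stopifnot(all(c("drug", "target", "confidence") %in% names(table)))
  if (any(table$confidence < 0 | table$confidence > 1))
    stop("'confidence' must lie in [0, 1]")
  if (anyDuplicated(table[, c("drug", "target")]))
    stop("duplicate (drug, target) rows")
  table[table$confidence >= min_conf, , drop = FALSE]
}

# Named list drug -> filtered target set, covering every library drug
# (possibly with empty sets).
target_sets <- function(table, library, min_conf = 0.8) {
  ft <- filter_targets(table, min_conf)
  sets <- split(ft$target, factor(ft$drug, levels = library))
  lapply(sets, unique)
}

#' Permutation p-value for shared drug targets
#'
#' Tests whether a drug pair shares more high-confidence targets than a
#' randomly chosen library pair. The observed statistic is the pair's
#' shared filtered-target count; the null repeatedly draws a uniformly
#' random pair of distinct library drugs — other than the tested pair
#' itself, which is resampled — and counts how often the random pair
#' shares at least as many targets. The empirical p-value uses the
#' add-one correction `p = (1 + exceedances) / (n_perm + 1)`, which avoids
#' exact zeros.
#'
#' @param drug_a,drug_b the pair to test; must belong to `library`.
#' @param table drug-target table (drug, target, confidence).
#' @param library character vector of library drug ids (>= 10).
#' @param min_conf confidence filter applied before counting.
#' @param n_perm number of random pair draws (default 10000).
#' @param seed RNG seed; results are deterministic under it.
#' @return list: `p_value`, `k_obs`, `n_perm`.
#' @export
shared_target_pvalue <- function(drug_a, drug_b, table, library,
                                 min_conf = 0.8, n_perm = 10000,
                                 seed = 1) {
  library <- unique(library)
  if (length(library) < 10)
    stop("library must contain >= 10 drugs")
  if (!drug_a %in% library || !drug_b %in% library)
    stop("tested pair must belong to the library")
  sets <- target_sets(table, library, min_conf)
  all_targets <- unique(unlist(sets))
  k_obs <- length(intersect(sets[[drug_a]], sets[[drug_b]]))
  # drug x target incidence -> shared-count matrix, so each null draw is
  # a single lookup
  inc <- matrix(0L, length(library), max(1L, length(all_targets)),
                dimnames = list(library, NULL))
  for (d in library)
    inc[d, match(sets[[d]], all_targets)] <- 1L
  shared <- tcrossprod(inc)
  n <- length(library)
  ia <- match(drug_a, library)
  ib <- match(drug_b, library)
  with_seed(seed, {
    i <- sample.int(n, n_perm, replace = TRUE)
    j <- sample.int(n, n_perm, replace = TRUE)
    bad <- function(i, j) i == j | (pmin(i, j) == min(ia, ib) &
                                      pmax(i, j) == max(ia, ib))
    while (any(bad(i, j))) {
      eq <- bad(i, j)
      i[eq] <- sample.int(n, sum(eq), replace = TRUE)
      j[eq] <- sample.int(n, sum(eq), replace = TRUE)
    }
    exceed <- sum(shared[cbind(i, j)] >= k_obs)
    list(p_value = (1 + exceed) / (n_perm + 1), k_obs = k_obs,
         n_perm = n_perm)
  })
}

#' Library-wide similarity baselines
#'
#' For every library drug, the maximum number of shared high-confidence
#' targets and the maximum Tanimoto score against the effective drug set —
#' histogram-ready vectors for judging how unusual the effective drugs'
#' mutual similarity is against the whole library.
#'
#' @param effective character vector of effective drug ids.
#' @param library character vector of library drug ids.
#' @param fps `fingerprint_set` covering both sets.
#' @param table drug-target table covering both sets.
#' @param min_conf confidence filter for targets.
#' @return data.frame: `drug`, `max_shared_targets`, `max_ts`.
#' @export
library_baselines <- function(effective, library, fps, table,
                              min_conf = 0.8) {
  missing_fp <- setdiff(c(effective, library), rownames(fps))
  if (length(missing_fp) > 0)
    stop("fingerprints missing for: ",
         paste(utils::head(missing_fp, 5), collapse = ", "))
  sets <- target_sets(table, unique(c(effective, library)), min_conf)
  fpm <- (unclass(fps) != 0) * 1L
  out <- data.frame(drug = library, max_shared_targets = 0L,
                    max_ts = NA_real_, stringsAsFactors = FALSE)
  for (ii in seq_along(library)) {
    d <- library[ii]
    out$max_shared_targets[ii] <- max(vapply(effective, function(e)
      length(intersect(sets[[d]], sets[[e]])), integer(1)))
    a <- fpm[d, ]
    out$max_ts[ii] <- max(vapply(effective, function(e)
      tanimoto(a, fpm[e, ]), numeric(1)))
  }
  out
}

#' Correlations between similarity metrics and efficacy similarity
#'
#' Pearson correlation, across drug pairs, between each similarity metric
#' (e.g. Tanimoto score, shared-target or shared-DEG Jaccard index) and
#' the efficiency similarity.
#'
#' @param pairs data.frame with one row per drug pair.
#' @param metrics names of metric columns.
#' @param response name of the efficacy-similarity column.
#' @return named numeric vector of correlations.
#' @export
similarity_correlations <- function(pairs, metrics,
                                    response = "eff_sim") {
  stopifnot(all(c(metrics, response) %in% names(pairs)))
  if (nrow(pairs) < 3)
    stop("need >= 3 drug pairs")
  y <- pairs[[response]]
  if (stats::sd(y) == 0)
    stop("degenerate (constant) response column")
  vapply(metrics, function(mcol) {
    x <- pairs[[mcol]]
    if (stats::sd(x) == 0)
      stop("degenerate (constant) metric column: ", mcol)
    stats::cor(x, y)
  }, numeric(1))
}
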