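#' Error model from untreated replicates
#'
#' Fits the per-gene reference mean and sample standard deviation over the
#' untreated replicate columns (drug == "control"). The 3-sigma
#' differential rule and the divergent-convergent classification are both
#' judged against this model.
#'
#' @param data an [expr_dataset()] containing >= 2 control columns.
#' @return list of class `control_model`: `mean` and `sd` (named per-gene
#'   vectors) and `n_replicates`.
#' @export
fit_control_model <- function(data) {
  cc <- control_columns(data)
  if (length(cc) < 2)
    stop("need >= 2 untreated replicate columns to fit the error model")
  x <- data$values[, cc, drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  structure(list(mean = m, sd = s, n_replicates = length(cc)),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat("Control error model:", length(x$mean), "genes from",
      x$n_replicates, "replicates; median sigma =",
      signif(stats::median(x$sd), 3), "\n")
  invisible(x)
}

#' Detection filter
#'
#' Keeps a gene when its detection p-value is `<= alpha` for at least one
#' sample anywhere in the time series (controls or any drug's course) —
#' expression consistently below the array's background control is treated
#' as unreliable signal.
#'
#' @param data an [expr_dataset()].
#' @param alpha detection p-value cutoff (default 0.05).
#' @return the filtered [expr_dataset()].
#' @export
filter_detected <- function(data, alpha = 0.05) {
  if (is.null(data$detection))
    stop("dataset has no detection p-value matrix")
  keep <- apply(data$detection, 1, min) <= alpha
  subset_genes(data, which(keep))
}

#' 3-sigma differential call
#'
#' A gene is called up/down-regulated in a sample when its expression
#' deviates from the control mean by strictly more than `k` control SDs:
#' `|x_i - mean_i^0| > k * sigma_i^0`.
#'
#' @param x numeric vector (or matrix with gene rownames) of expression
#'   values; names identify genes in the model.
#' @param model a [fit_control_model()] result.
#' @param genes gene ids aligning `x` with the model; defaults to
#'   `names(x)` / `rownames(x)`.
#' @param k SD multiplier (default 3).
#' @return logical vector (or matrix) of differential flags.
#' @export
is_differential <- function(x, model, genes = NULL, k = 3) {
  if (is.null(genes))
    genes <- if (is.matrix(x)) rownames(x) else names(x)
  if (is.null(genes))
    stop("cannot align 'x' with the model: no gene ids")
  bad <- setdiff(genes, names(model$mean))
  if (length(bad) > 0)
    stop("genes absent from the control model: ",
         paste(utils::head(bad, 5), collapse = ", "))
  s <- model$sd[genes]
  if (any(s == 0))
    stop("sigma^0 = 0, differential test undefined for gene(s): ",
         paste(utils::head(genes[s == 0], 5), collapse = ", "))
  abs(x - model$mean[genes]) > k * s
}

#' Pairwise between-drug expression differences
#'
#' For every gene and every unordered pair of drugs (a, b), the absolute
#' difference `|x_i^a(t) - x_i^b(t)|` at day `t`. With D drugs there are
#' M = D(D-1)/2 pairs (120 for 16 drugs).
#'
#' @param data an [expr_dataset()].
#' @param day time point at which to compare drugs.
#' @param drugs drugs to compare (default: all treated drugs).
#' @return genes x M matrix of class `pairwise_diffs`; columns are named
#'   `"a|b"`; attributes `day` and `drugs`.
#' @export
pairwise_diffs <- function(data, day, drugs = treated_drugs(data)) {
  if (length(drugs) < 2)
    stop("need >= 2 drugs measured at day ", day)
  x <- day_matrix(data, day, drugs)           # errors on missing samples
  idx <- utils::combn(length(drugs), 2)
  d <- abs(x[, idx[1, ], drop = FALSE] - x[, idx[2, ], drop = FALSE])
  colnames(d) <- paste(drugs[idx[1, ]], drugs[idx[2, ]], sep = "|")
  structure(d, day = day, drugs = drugs,
            class = c("pairwise_diffs", class(d)))
}

#' Divergent-convergent classification
#'
#' A gene follows the divergent-convergent pattern when its mean pairwise
#' between-drug difference `(1/M) sum_m d_i^m` exceeds `k` control SDs at
#' one of the intermediate days but falls strictly below `k` SDs at the
#' final day (divergence of the drug trajectories followed by
#' convergence). Genes with `sigma^0 = 0` are excluded (flag `NA`) and
#' counted in the `n_excluded` attribute, with a warning.
#'
#' @param diffs list of [pairwise_diffs()] matrices in increasing day
#'   order; the last entry is the convergence (final) day.
#' @param model a [fit_control_model()] result.
#' @param k SD multiplier (default 3).
#' @return named logical vector of per-gene flags, attribute `n_excluded`.
#' @export
classify_divergent_convergent <- function(diffs, model, k = 3) {
  if (length(diffs) < 2)
    stop("need pairwise differences for at least two days")
  days <- vapply(diffs, function(d) as.numeric(attr(d, "day")), numeric(1))
  if (any(diff(days) <= 0))
    stop("'diffs' must be ordered by increasing day")
  genes <- rownames(diffs[[1]])
  for (d in diffs[-1])
    if (!identical(rownames(d), genes))
      stop("all pairwise-difference matrices must cover the same genes")
  mean_d <- vapply(diffs, rowMeans, numeric(length(genes)))
  s <- model$sd[genes]
  n_early <- length(diffs) - 1
  early_high <- rowSums(mean_d[, seq_len(n_early), drop = FALSE] >
                          k * s) > 0
  final_low <- mean_d[, n_early + 1] < k * s
  flag <- early_high & final_low
  names(flag) <- genes
  excluded <- !is.finite(s) | s == 0
  if (any(excluded)) {
    flag[excluded] <- NA
    warning(sum(excluded),
            " gene(s) with sigma^0 = 0 excluded from classification")
  }
  structure(flag, n_excluded = sum(excluded))
}

#' Assign trajectory categories C1-C5
#'
#' Combines three per-gene flags into the category labels:
#' \itemize{
#'   \item N (net change): differential (3-sigma rule) at the final day in
#'     more than `majority_fraction` of the drugs;
#'   \item T (transient): differential at some intermediate day in more
#'     than `majority_fraction` of the drugs, but not N;
#'   \item D (divergent-convergent): from
#'     [classify_divergent_convergent()].
#' }
#' Labels: C1 = D and not N; C3 = D and N; C4 = N without D; C2 = T
#' without D; C5 = any remaining gene differential in at least one drug at
#' at least one day; background otherwise. Genes excluded from the D flag
#' (`sigma^0 = 0`) receive label `NA`.
#'
#' @param data an [expr_dataset()] (filtered).
#' @param model a [fit_control_model()] result.
#' @param dc_flags optional result of [classify_divergent_convergent()];
#'   computed from `data` when `NULL`.
#' @param k SD multiplier for the differential rule (default 3).
#' @param majority_fraction quorum of drugs for the N and T flags
#'   (default 0.5).
#' @return data.frame of class `category_assignment`: `gene`, `label`,
#'   `divergent`, `net_changed`, `transient`; attribute `n_excluded`.
#' @export
assign_categories <- function(data, model, dc_flags = NULL, k = 3,
                              majority_fraction = 0.5) {
  genes <- rownames(data$values)
  drugs <- treated_drugs(data)
  td <- treated_days(data)
  n_final <- td[length(td)]
  s <- model$sd[genes]
  ok <- is.finite(s) & s > 0
  if (is.null(dc_flags)) {
    diffs <- lapply(td, function(d) pairwise_diffs(data, d, drugs))
    dc_flags <- suppressWarnings(
      classify_divergent_convergent(diffs, model, k))
  }
  dc_flags <- dc_flags[genes]

  # genes x drugs differential indicator per day (only sigma > 0 genes)
  diff_at <- function(day) {
    x <- day_matrix(data, day, drugs)[ok, , drop = FALSE]
    is_differential(x, model, k = k)
  }
  final_diff <- diff_at(n_final)
  early_any <- matrix(FALSE, sum(ok), length(drugs))
  for (day in td[-length(td)])
    early_any <- early_any | diff_at(day)

  N <- Tt <- D <- any_diff <- rep(NA, length(genes))
  names(N) <- names(Tt) <- names(D) <- names(any_diff) <- genes
  N[ok] <- rowMeans(final_diff) > majority_fraction
  Tt[ok] <- rowMeans(early_any) > majority_fraction & !N[ok]
  D[ok] <- dc_flags[ok]
  any_diff[ok] <- rowSums(final_diff | early_any) > 0

  label <- rep(NA_character_, length(genes))
  usable <- ok & !is.na(D)
  label[usable & D & !N] <- "C1"
  label[usable & D & N] <- "C3"
  label[usable & !D & N] <- "C4"
  label[usable & !D & Tt] <- "C2"
  label[usable & is.na(label) & any_diff] <- "C5"
  label[usable & is.na(label)] <- "background"

  out <- data.frame(gene = genes, label = label, divergent = D,
                    net_changed = N, transient = Tt,
                    stringsAsFactors = FALSE)
  structure(out, n_excluded = sum(!usable),
            class = c("category_assignment", class(out)))
}

#' @export
print.category_assignment <- function(x, ...) {
  counts <- table(factor(x$label,
                         levels = c("C1", "C2", "C3", "C4", "C5",
                                    "background")))
  cat("Trajectory category assignment over", nrow(x), "genes\n")
  print(counts)
  ne <- attr(x, "n_excluded")
  if (ne > 0) cat("  excluded (sigma^0 = 0):", ne, "\n")
  invisible(x)
}

#' Modified Pearson correlation
#'
#' Pearson-form correlation between two same-day samples in which each
#' gene's deviation is taken from its own temporal mean over a drug's time
#' course (Day 0 = control mean, then the treated days) rather than from
#' the sample-wide mean:
#' `r = sum_i (a_i - m_i^a)(b_i - m_i^b) / (||a - m^a|| ||b - m^b||)`.
#' When the supplied means equal each sample's cross-gene mean, this
#' reduces to the standard Pearson correlation.
#'
#' @param a,b expression vectors on a common gene set (length >= 2).
#' @param means_a per-gene temporal means for the drug sample `a` belongs
#'   to.
#' @param means_b temporal means for `b`'s drug; defaults to `means_a`.
#' @return correlation in \[-1, 1\].
#' @export
modified_pearson <- function(a, b, means_a, means_b = means_a) {
  n <- length(a)
  if (n < 2 || length(b) != n || length(means_a) != n ||
      length(means_b) != n)
    stop("'a', 'b' and the temporal means must share one length >= 2")
  da <- a - means_a
  db <- b - means_b
  na2 <- sum(da^2)
  nb2 <- sum(db^2)
  if (na2 == 0 || nb2 == 0)
    stop("degenerate sample: zero deviation norm")
  r <- sum(da * db) / sqrt(na2 * nb2)
  min(1, max(-1, r))
}

# Per-gene temporal means for each drug's course: Day 0 (control mean)
# plus the drug's treated-day samples. genes x drugs matrix.
drug_temporal_means <- function(data, model,
                                drugs = treated_drugs(data)) {
  td <- treated_days(data)
  genes <- rownames(data$values)
  tm <- vapply(drugs, function(d) {
    cols <- vapply(td, function(day) sample_column(data, d, day),
                   integer(1))
    rowMeans(cbind(model$mean[genes], data$values[, cols, drop = FALSE]))
  }, numeric(length(genes)))
  rownames(tm) <- genes
  tm
}

#' Transcriptome dispersion by day
#'
#' All pairwise modified-Pearson correlations between same-day samples of
#' different drugs, each sample's deviations taken from its own drug's
#' temporal means. Low mean correlation at a day indicates dispersed
#' (divergent) transcriptomes.
#'
#' @param data an [expr_dataset()].
#' @param model a [fit_control_model()] result.
#' @param drugs drugs to include (default: all treated drugs).
#' @return data.frame: `day`, `drug_a`, `drug_b`, `r`.
#' @export
dispersion_by_day <- function(data, model, drugs = treated_drugs(data)) {
  if (length(drugs) < 2)
    stop("need >= 2 drugs per day")
  tm <- drug_temporal_means(data, model, drugs)
  td <- treated_days(data)
  idx <- utils::combn(length(drugs), 2)
  out <- lapply(td, function(day) {
    dev <- day_matrix(data, day, drugs) - tm
    cp <- crossprod(dev)
    dg <- diag(cp)
    if (any(dg == 0))
      stop("degenerate sample: zero deviation norm at day ", day)
    r <- cp[cbind(idx[1, ], idx[2, ])] / sqrt(dg[idx[1, ]] * dg[idx[2, ]])
    data.frame(day = day, drug_a = drugs[idx[1, ]],
               drug_b = drugs[idx[2, ]], r = pmin(1, pmax(-1, r)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-subsampled dispersion distributions
#'
#' Repeats [dispersion_by_day()] on random gene subsets (500 genes, 100
#' repetitions by default) to assess the statistical robustness of the
#' divergence-convergence pattern against gene sampling. Deterministic
#' under `seed`.
#'
#' @param data an [expr_dataset()] with at least `n_genes` genes.
#' @param model a [fit_control_model()] result.
#' @param n_genes subset size per repetition.
#' @param n_reps number of repetitions.
#' @param seed RNG seed.
#' @return data.frame: `rep`, `day`, `drug_a`, `drug_b`, `r`.
#' @export
subsample_dispersion <- function(data, model, n_genes = 500,
                                 n_reps = 100, seed = 1) {
  if (n_genes > nrow(data$values))
    stop("'n_genes' exceeds the number of available genes")
  drugs <- treated_drugs(data)
  td <- treated_days(data)
  tm <- drug_temporal_means(data, model, drugs)
  devs <- lapply(td, function(day) day_matrix(data, day, drugs) - tm)
  idx <- utils::combn(length(drugs), 2)
  with_seed(seed, {
    out <- vector("list", n_reps)
    for (rep_i in seq_len(n_reps)) {
      rows <- sample.int(nrow(data$values), n_genes)
      per_day <- lapply(seq_along(td), function(k) {
        cp <- crossprod(devs[[k]][rows, , drop = FALSE])
        dg <- diag(cp)
        r <- cp[cbind(idx[1, ], idx[2, ])] /
          sqrt(dg[idx[1, ]] * dg[idx[2, ]])
        data.frame(rep = rep_i, day = td[k], drug_a = drugs[idx[1, ]],
                   drug_b = drugs[idx[2, ]], r = pmin(1, pmax(-1, r)),
                   stringsAsFactors = FALSE)
      })
      out[[rep_i]] <- do.call(rbind, per_day)
    }
    do.call(rbind, out)
  })
}

#' PCA projection of samples
#'
#' Centered principal-component projection of the sample x gene matrix,
#' for visualizing the divergence-convergence of the transcriptome
#' trajectories in the space of the top components.
#'
#' @param data an [expr_dataset()].
#' @param n_components number of components to return (default 3).
#' @return list of class `pca_projection`: `scores` (data.frame with
#'   sample metadata and PC coordinates) and `explained_variance`
#'   (fractions for the returned components).
#' @export
pca_project <- function(data, n_components = 3) {
  x <- t(data$values)
  if (nrow(x) < n_components)
    stop("need at least 'n_components' samples")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  kk <- min(n_components, ncol(pr$x))
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- data.frame(data$meta, pr$x[, seq_len(kk), drop = FALSE],
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, explained_variance = ev[seq_len(kk)]),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("PCA projection:", nrow(x$scores), "samples;",
      "explained variance:",
      paste(signif(x$explained_variance, 3), collapse = ", "), "\n")
  invisible(x)
}
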