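#' Expression dataset container
#'
#' Bundles a genes x samples matrix of log2 expression intensities with a
#' detection p-value matrix of identical shape and per-sample metadata
#' (drug, dose, day). Untreated replicate controls are the rows of `meta`
#' whose `drug` equals `"control"`; they stand for Day 0 of every drug's
#' time course.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param detection numeric matrix of detection p-values, same dimensions
#'   and dimnames as `values`.
#' @param meta data.frame with columns `sample_id`, `drug`, `dose`, `day`;
#'   one row per column of `values`.
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, detection, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  stopifnot(is.matrix(detection), identical(dim(values), dim(detection)))
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "drug", "day") %in% names(meta)))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (!identical(colnames(values), as.character(meta$sample_id)))
    stop("metadata rows must match value columns (same sample ids, same order)")
  if (!"dose" %in% names(meta)) meta$dose <- NA_real_
  structure(list(values = values, detection = detection, meta = meta),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  trt <- x$meta$drug != "control"
  cat("Expression dataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("  controls:", sum(!trt),
      " drugs:", length(unique(x$meta$drug[trt])),
      " days:", paste(sort(unique(x$meta$day[trt])), collapse = ","), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# --- internal accessors -----------------------------------------------------

control_columns <- function(data) {
  which(data$meta$drug == "control")
}

treated_drugs <- function(data) {
  sort(unique(data$meta$drug[data$meta$drug != "control"]))
}

treated_days <- function(data) {
  sort(unique(data$meta$day[data$meta$drug != "control"]))
}

# Column index of the sample for (drug, day); errors if absent.
sample_column <- function(data, drug, day) {
  idx <- which(data$meta$drug == drug & data$meta$day == day)
  if (length(idx) == 0)
    stop(sprintf("no sample for drug '%s' at day %s", drug, day))
  idx[1]
}

# genes x drugs matrix of expression at one day (one sample per drug).
day_matrix <- function(data, day, drugs = treated_drugs(data)) {
  cols <- vapply(drugs, function(d) sample_column(data, d, day), integer(1))
  m <- data$values[, cols, drop = FALSE]
  colnames(m) <- drugs
  m
}

# Keep a subset of genes.
subset_genes <- function(data, genes) {
  expr_dataset(data$values[genes, , drop = FALSE],
               data$detection[genes, , drop = FALSE],
               data$meta)
}
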