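#' Read and write pipeline file formats
#'
#' Plain-text interchange formats: expression matrix TSV (gene rows, sample
#' columns) with companion metadata and detection-p TSVs, PPI edge-list
#' TSV, drug-target TSV, fingerprints as hex strings, screen CSV and
#' ground-truth JSON. The same readers handle exported real matrices with
#' the same column layout.
#'
#' @param data an [expr_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return `write_expression_dataset()` returns the written paths
#'   invisibly; `read_expression_dataset()` returns an [expr_dataset()].
#' @export
write_expression_dataset <- function(data, dir, prefix = "expr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, paste0(prefix, ".tsv"))
  p_det <- file.path(dir, paste0(prefix, "_detection.tsv"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.tsv"))
  write_matrix_tsv(data$values, p_expr)
  write_matrix_tsv(data$detection, p_det)
  utils::write.table(data$meta, p_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values = p_expr, detection = p_det, meta = p_meta))
}

#' @param values_path,detection_path,meta_path paths written by
#'   `write_expression_dataset()`.
#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(values_path, detection_path, meta_path) {
  values <- read_matrix_tsv(values_path)
  detection <- read_matrix_tsv(detection_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expr_dataset(values, detection, meta)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @param network a `ppi_network`.
#' @param path file path.
#' @rdname write_expression_dataset
#' @export
write_ppi_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_ppi_network <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(edges)[1:3] <- c("nodeA", "nodeB", "confidence")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$nodeA, edges$nodeB)))),
            class = "ppi_network")
}

#' @param table a drug-target or screen table.
#' @rdname write_expression_dataset
#' @export
write_drug_targets <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_drug_targets <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_expression_dataset
#' @export
write_screen_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_screen_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param fps a `fingerprint_set` matrix.
#' @rdname write_expression_dataset
#' @export
write_fingerprints <- function(fps, path) {
  hex <- apply(fps, 1, bits_to_hex)
  df <- data.frame(drug = rownames(fps), n_bits = ncol(fps), fingerprint = hex,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  n_bits <- unique(df$n_bits)
  if (length(n_bits) != 1)
    stop("all fingerprints in a set must share one length")
  fp <- t(vapply(df$fingerprint, hex_to_bits, integer(n_bits), n_bits))
  rownames(fp) <- df$drug
  structure(fp, class = c("fingerprint_set", class(fp)))
}

bits_to_hex <- function(bits) {
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(as.integer(bits), rep(0L, pad))
  nib <- matrix(bits, nrow = 4)
  vals <- as.integer(8L * nib[1, ] + 4L * nib[2, ] + 2L * nib[3, ] + nib[4, ])
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- as.vector(vapply(vals, function(v)
    as.integer(c(v %/% 8 %% 2, v %/% 4 %% 2, v %/% 2 %% 2, v %% 2)),
    integer(4)))
  bits[seq_len(n_bits)]
}

#' @param truth a `ground_truth` list.
#' @rdname write_expression_dataset
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$categories))
    x$categories <- as.list(x$categories)   # keep gene names in JSON
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$categories))
    raw$categories <- unlist(raw$categories)
  structure(raw, class = "ground_truth")
}
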