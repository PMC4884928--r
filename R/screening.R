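#' Z-scores for a differentiation screen
#'
#' Standardizes each drug's differentiation efficiency (percent
#' lipid-positive cells) and viability (live-cell count) at a reference
#' dose against the whole library at that dose:
#' z = (x - mean_library) / sd_library, with the sample (n - 1) SD.
#'
#' @param table screen table: columns `drug`, `dose`, `pct_differentiated`,
#'   `live_cells`, one row per (drug, dose).
#' @param dose reference dose; defaults to the top dose in the table. Only
#'   this dose gates selection; the other doses ride along in the table.
#' @return data.frame with one row per drug: `drug`, `pct_differentiated`,
#'   `live_cells`, `z_diff`, `z_tox`.
#' @export
compute_zscores <- function(table, dose = max(table$dose)) {
  stopifnot(all(c("drug", "dose", "pct_differentiated", "live_cells")
                %in% names(table)))
  if (any(table$pct_differentiated < 0 | table$pct_differentiated > 100))
    stop("'pct_differentiated' must lie in [0, 100]")
  if (any(table$live_cells < 0))
    stop("'live_cells' must be non-negative")
  sub <- table[table$dose == dose, , drop = FALSE]
  if (nrow(sub) < 2)
    stop(sprintf("need >= 2 drugs measured at dose %s", dose))
  if (anyDuplicated(sub$drug))
    stop("more than one row per (drug, dose)")
  missing <- setdiff(unique(table$drug), sub$drug)
  if (length(missing) > 0)
    stop(sprintf("no dose-%s row for: %s", dose,
                 paste(missing, collapse = ", ")))
  z <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero SD of %s across the library at dose %s: %s",
                   what, dose, "degenerate library"))
    (x - mean(x)) / s
  }
  data.frame(drug = sub$drug,
             pct_differentiated = sub$pct_differentiated,
             live_cells = sub$live_cells,
             z_diff = z(sub$pct_differentiated, "pct_differentiated"),
             z_tox = z(sub$live_cells, "live_cells"),
             stringsAsFactors = FALSE)
}

#' Select effective, non-toxic drugs
#'
#' Dual-criterion hit calling: a drug is effective when its
#' differentiation Z-score exceeds `diff_threshold` (default 1.8) and its
#' viability Z-score exceeds `tox_threshold` (default -1, excluding toxic
#' compounds). Returns hits stable-sorted by decreasing `z_diff`.
#'
#' @param calls output of [compute_zscores()].
#' @param diff_threshold minimum differentiation Z-score.
#' @param tox_threshold minimum viability Z-score.
#' @return character vector of selected drug ids.
#' @export
select_effective <- function(calls, diff_threshold = 1.8,
                             tox_threshold = -1) {
  stopifnot(all(c("drug", "z_diff", "z_tox") %in% names(calls)))
  hit <- calls$z_diff > diff_threshold & calls$z_tox > tox_threshold
  sel <- calls[hit, , drop = FALSE]
  sel$drug[order(-sel$z_diff)]
}
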