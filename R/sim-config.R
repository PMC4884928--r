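#' Simulation configuration
#'
#' Parameters for the synthetic-data generators. Defaults mirror the study
#' design that the package emulates: 16 drugs profiled at days 1, 3 and 5
#' against a pool of 14 untreated replicate arrays, with planted trajectory
#' categories, a planted common pathway in the interaction network, and
#' planted effective drugs in the differentiation screen.
#'
#' @param n_genes number of genes.
#' @param n_drugs number of profiled drugs.
#' @param n_controls number of untreated replicate arrays (>= 2).
#' @param days measurement days; must start at 0 and be strictly increasing.
#'   Day 0 is represented by the shared control pool.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensity.
#' @param noise_sd replicate noise SD per gene on log2 scale (the sigma_i^0
#'   scale of the control error model).
#' @param effect_sd_multiplier planted effect size in units of `noise_sd`.
#' @param category_fractions named fractions for the planted trajectory
#'   categories C1..C5 plus `background`; must sum to 1.
#' @param undetected_fraction fraction of genes planted as never reliably
#'   detected (detection p-values uniform on \[0.05, 1\]); drawn from the
#'   background category.
#' @param ppi_nodes number of protein-interaction network nodes.
#' @param ppi_edge_prob Erdos-Renyi background edge probability.
#' @param ppi_model `"erdos_renyi"` (default) or `"barabasi_albert"` for the
#'   background topology.
#' @param planted_path_length number of edges in the planted backbone chain
#'   connecting the shared drug-target entry node to a planted DEG node.
#' @param targets_per_drug targets assigned to each drug (>= 1).
#' @param low_conf_fraction fraction of non-backbone drug-target rows drawn
#'   with confidence below 0.8, to exercise the confidence filter.
#' @param fingerprint_bits fingerprint length in bits (>= 8).
#' @param fingerprint_density expected fraction of set bits.
#' @param seed integer seed; same seed implies bit-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_drugs = 16L,
                       n_controls = 14L,
                       days = c(0, 1, 3, 5),
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       noise_sd = 0.2,
                       effect_sd_multiplier = 6,
                       category_fractions = c(C1 = 0.10, C2 = 0.05,
                                              C3 = 0.10, C4 = 0.10,
                                              C5 = 0.05, background = 0.60),
                       undetected_fraction = 0.05,
                       ppi_nodes = 200L,
                       ppi_edge_prob = 0.02,
                       ppi_model = c("erdos_renyi", "barabasi_albert"),
                       planted_path_length = 3L,
                       targets_per_drug = 2L,
                       low_conf_fraction = 0.2,
                       fingerprint_bits = 1024L,
                       fingerprint_density = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_drugs = as.integer(n_drugs),
              n_controls = as.integer(n_controls),
              days = as.numeric(days),
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              noise_sd = noise_sd,
              effect_sd_multiplier = effect_sd_multiplier,
              category_fractions = category_fractions,
              undetected_fraction = undetected_fraction,
              ppi_nodes = as.integer(ppi_nodes),
              ppi_edge_prob = ppi_edge_prob,
              ppi_model = match.arg(ppi_model),
              planted_path_length = as.integer(planted_path_length),
              targets_per_drug = as.integer(targets_per_drug),
              low_conf_fraction = low_conf_fraction,
              fingerprint_bits = as.integer(fingerprint_bits),
              fingerprint_density = fingerprint_density,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_drugs", "n_controls", "ppi_nodes",
              "planted_path_length", "targets_per_drug", "fingerprint_bits")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be a positive count", nm))
  }
  if (cfg$n_controls < 2)
    stop("'n_controls' must be >= 2 (replicate SD undefined otherwise)")
  fr <- cfg$category_fractions
  wanted <- c("C1", "C2", "C3", "C4", "C5", "background")
  if (!setequal(names(fr), wanted))
    stop("'category_fractions' must be named C1..C5 and background")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("'category_fractions' must be non-negative and sum to 1")
  d <- cfg$days
  if (d[1] != 0 || length(d) < 2 || any(diff(d) <= 0))
    stop("'days' must be strictly increasing and start at 0")
  if (cfg$ppi_edge_prob < 0 || cfg$ppi_edge_prob > 1)
    stop("'ppi_edge_prob' must lie in [0, 1]")
  if (cfg$ppi_nodes < cfg$planted_path_length + 2)
    stop("'ppi_nodes' must be at least planted_path_length + 2")
  if (cfg$fingerprint_bits < 8)
    stop("'fingerprint_bits' must be >= 8")
  if (cfg$undetected_fraction < 0 || cfg$undetected_fraction >= 1)
    stop("'undetected_fraction' must lie in [0, 1)")
  if (cfg$low_conf_fraction < 0 || cfg$low_conf_fraction > 1)
    stop("'low_conf_fraction' must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes,", x$n_drugs, "drugs,",
      x$n_controls, "controls, days", paste(x$days, collapse = ","), "\n")
  cat("  effect:", x$effect_sd_multiplier, "x noise_sd =",
      x$effect_sd_multiplier * x$noise_sd, "log2 units; seed", x$seed, "\n")
  invisible(x)
}
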