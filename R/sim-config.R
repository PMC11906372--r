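#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the
#' reference simulation used throughout the package's validation: an
#' 8-cell-type atlas of 200 cells per type and 2,000 genes plus 60
#' transcription factors, one planted safeguard repressor and one planted
#' activator per type, an 8-fold marker effect, and promoter motif rates of
#' 0.2 (depleted) vs 3.0 (enriched) mean hits per promoter.
#'
#' @param n_cell_types number of cell types in the atlas.
#' @param cells_per_type cells simulated per cell type.
#' @param n_genes number of non-TF genes.
#' @param n_tfs number of transcription factors.
#' @param markers_per_type planted marker genes per cell type.
#' @param safeguard_per_type planted safeguard repressor TFs per cell type.
#' @param activator_per_type planted activator TFs per cell type.
#' @param marker_fold expression fold-up of a marker (or planted TF) in its
#'   home cell type; `1` plants no effect.
#' @param motif_rate_high mean motif hits per enriched promoter.
#' @param motif_rate_low mean motif hits per depleted promoter.
#' @param noise_dispersion negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2).
#' @param transduction_rate probability that an overexpression-condition
#'   cell is truly transduced in the reprogramming simulation.
#' @param repression_factor multiplier applied to regulon-target mean
#'   expression in transduced cells; in (0, 1], `1` means no repression.
#' @param seed integer seed; the generator is bit-reproducible given
#'   (config, seed).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 8L, cells_per_type = 200L,
                       n_genes = 2000L, n_tfs = 60L,
                       markers_per_type = 100L,
                       safeguard_per_type = 1L, activator_per_type = 1L,
                       marker_fold = 8, motif_rate_high = 3.0,
                       motif_rate_low = 0.2, noise_dispersion = 0.3,
                       transduction_rate = 0.7, repression_factor = 0.2,
                       seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              markers_per_type = as.integer(markers_per_type),
              safeguard_per_type = as.integer(safeguard_per_type),
              activator_per_type = as.integer(activator_per_type),
              marker_fold = as.numeric(marker_fold),
              motif_rate_high = as.numeric(motif_rate_high),
              motif_rate_low = as.numeric(motif_rate_low),
              noise_dispersion = as.numeric(noise_dispersion),
              transduction_rate = as.numeric(transduction_rate),
              repression_factor = as.numeric(repression_factor),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param cfg a configuration list to validate; errors name the violated
#'   invariant.
#' @export
validate_sim_config <- function(cfg) {
  counts <- c("n_cell_types", "cells_per_type", "n_genes", "n_tfs",
              "markers_per_type", "safeguard_per_type", "activator_per_type")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_config("invalid config: %s must be a count >= 1", f)
  if (cfg$safeguard_per_type + cfg$activator_per_type >
      cfg$n_tfs / cfg$n_cell_types)
    stop_config(paste("invalid config: safeguard_per_type + activator_per_type",
                      "exceeds n_tfs / n_cell_types"))
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_genes)
    stop_config("invalid config: markers_per_type * n_cell_types exceeds n_genes")
  if (cfg$marker_fold <= 0)
    stop_config("invalid config: marker_fold must be positive")
  if (cfg$motif_rate_high <= 0)
    stop_config("invalid config: motif_rate_high must be positive")
  if (cfg$motif_rate_low < 0)
    stop_config("invalid config: motif_rate_low must be non-negative")
  if (cfg$noise_dispersion <= 0)
    stop_config("invalid config: noise_dispersion must be positive")
  if (cfg$transduction_rate < 0 || cfg$transduction_rate > 1)
    stop_config("invalid config: transduction_rate must lie in [0, 1]")
  if (cfg$repression_factor <= 0 || cfg$repression_factor > 1)
    stop_config("invalid config: repression_factor must lie in (0, 1]")
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror [sim_config()] exactly; absent fields take the
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
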