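# Synthetic-data generator: a multi-cell-type expression atlas with planted
# cell-type-specific activator and safeguard-repressor TFs, promoter motif
# hits with planted depletion/enrichment structure, aged and developmental
# expression series, and a two-condition reprogramming dataset with latent
# transduction status. Every generator is bit-reproducible given
# (config, seed); sub-stages draw from independent derived seeds.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

sim_ids <- function(cfg) {
  list(genes = sprintf("gene%04d", seq_len(cfg$n_genes)),
       tfs   = sprintf("tf%02d", seq_len(cfg$n_tfs)),
       types = sprintf("type%02d", seq_len(cfg$n_cell_types)))
}

# Baseline (cell-type-independent) mean expression per feature, lognormal
# across features as is typical of UMI data; shared by the young atlas, the
# aged atlas and the reprogramming dataset so series are comparable.
sim_base_means <- function(cfg) {
  ids <- sim_ids(cfg)
  mu <- with_local_seed(derive_seed(cfg$seed, 1L),
                        stats::rlnorm(cfg$n_genes + cfg$n_tfs,
                                      meanlog = 0, sdlog = 1))
  names(mu) <- c(ids$genes, ids$tfs)
  mu
}

#' Planted ground truth of a simulation
#'
#' Assigns each cell type its marker genes (sampled without replacement)
#' and its safeguard-repressor and activator TFs (assigned in blocks);
#' remaining TFs are neutral. Roles are disjoint and each planted TF has
#' exactly one home type.
#'
#' @param cfg a [sim_config()].
#' @return `planted_truth`: list with `tf_role` (tf, role, home_type),
#'   `marker_assignment` (gene, home_type), and placeholders `transduced`
#'   and `regulon` filled by [simulate_reprogramming()].
#' @export
plant_truth <- function(cfg) {
  validate_sim_config(cfg)
  ids <- sim_ids(cfg)
  per <- cfg$safeguard_per_type + cfg$activator_per_type
  role <- rep("neutral", cfg$n_tfs)
  home <- rep(NA_character_, cfg$n_tfs)
  for (t in seq_len(cfg$n_cell_types)) {
    block <- (t - 1L) * per + seq_len(per)
    role[block] <- rep(c("safeguard", "activator"),
                       c(cfg$safeguard_per_type, cfg$activator_per_type))
    home[block] <- ids$types[t]
  }
  markers <- with_local_seed(derive_seed(cfg$seed, 2L),
                             sample(ids$genes,
                                    cfg$markers_per_type * cfg$n_cell_types))
  marker_home <- rep(ids$types, each = cfg$markers_per_type)
  structure(list(
    tf_role = data.frame(tf = ids$tfs, role = role, home_type = home,
                         stringsAsFactors = FALSE),
    marker_assignment = data.frame(gene = markers, home_type = marker_home,
                                   stringsAsFactors = FALSE),
    transduced = NULL, regulon = NULL),
    class = "planted_truth")
}

# Per-cell mean matrix of the young atlas: baseline means with markers and
# planted TFs multiplied by marker_fold in their home type.
sim_mu_matrix <- function(cfg, truth, tf_scale = NULL) {
  ids <- sim_ids(cfg)
  base <- sim_base_means(cfg)
  if (!is.null(tf_scale)) base[names(tf_scale)] <- base[names(tf_scale)] * tf_scale
  n_cells <- cfg$n_cell_types * cfg$cells_per_type
  mu <- matrix(base, nrow = length(base), ncol = n_cells,
               dimnames = list(names(base),
                               sprintf("cell%04d", seq_len(n_cells))))
  labels <- rep(ids$types, each = cfg$cells_per_type)
  fold_map <- rbind(
    data.frame(id = truth$marker_assignment$gene,
               home = truth$marker_assignment$home_type),
    data.frame(id = truth$tf_role$tf[truth$tf_role$role != "neutral"],
               home = truth$tf_role$home_type[truth$tf_role$role != "neutral"]))
  for (t in ids$types) {
    sel <- fold_map$id[fold_map$home == t]
    mu[sel, labels == t] <- mu[sel, labels == t] * cfg$marker_fold
  }
  list(mu = mu, labels = stats::setNames(factor(labels, levels = ids$types),
                                         colnames(mu)))
}

rnbinom_matrix <- function(mu, dispersion) {
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  counts
}

#' Simulate a labeled expression atlas with planted TF roles
#'
#' Counts are negative-binomial around cell-type-dependent means: each
#' marker gene and each planted (safeguard or activator) TF has its mean
#' multiplied by `marker_fold` in its home cell type.
#'
#' @param cfg a [sim_config()].
#' @return list with `atlas` (a raw-counts [cell_atlas()] of
#'   `n_genes + n_tfs` rows) and `truth` (a [plant_truth()] object).
#' @export
simulate_atlas <- function(cfg) {
  validate_sim_config(cfg)
  truth <- plant_truth(cfg)
  mm <- sim_mu_matrix(cfg, truth)
  counts <- with_local_seed(derive_seed(cfg$seed, 3L),
                            rnbinom_matrix(mm$mu, cfg$noise_dispersion))
  list(atlas = cell_atlas(counts, mm$labels, "raw"), truth = truth)
}

#' Synthetic TSS annotation
#'
#' One synthetic chromosome per `genes_per_chrom` features, TSS spaced
#' `spacing` bases apart starting at `spacing`, all on the `+` strand
#' (promoter windows downstream are symmetric, so strand is inert).
#'
#' @param gene_ids character vector of feature ids (genes and TFs).
#' @param genes_per_chrom,spacing layout parameters.
#' @return data.frame (gene, chrom, tss, strand).
#' @export
make_tss_annotation <- function(gene_ids, genes_per_chrom = 1000L,
                                spacing = 10000L) {
  n <- length(gene_ids)
  idx <- seq_len(n) - 1L
  data.frame(gene = gene_ids,
             chrom = sprintf("chr%d", idx %/% genes_per_chrom + 1L),
             tss = (idx %% genes_per_chrom + 1L) * spacing,
             strand = "+",
             stringsAsFactors = FALSE)
}

#' Simulate promoter motif hits with planted depletion structure
#'
#' For every TF and gene promoter the hit count is Poisson with mean
#' `motif_rate_low` where the planted structure dictates depletion
#' (safeguard TF at its own type's markers), `motif_rate_high` where it
#' dictates enrichment (safeguard TF at other types' markers), the reverse
#' for activators, and the midpoint of the two rates for neutral TFs and
#' non-marker genes. Hits are emitted as 11-base intervals placed uniformly
#' at random inside the +/-2 kb promoter window (0-based half-open).
#'
#' @param truth a [plant_truth()] object.
#' @param annotation TSS table from [make_tss_annotation()]; must cover
#'   every marker gene in `truth`.
#' @param cfg the [sim_config()].
#' @param flank promoter half-width in bases.
#' @param motif_width emitted hit width in bases.
#' @return data.frame (tf, chrom, start, end), 0-based half-open.
#' @export
simulate_motif_hits <- function(truth, annotation, cfg, flank = 2000L,
                                motif_width = 11L) {
  validate_sim_config(cfg)
  missing <- setdiff(truth$marker_assignment$gene, annotation$gene)
  if (length(missing))
    stop_data("annotation missing gene(s): %s",
              paste(utils::head(missing, 5L), collapse = ", "))
  genes <- annotation$gene
  marker_home <- stats::setNames(truth$marker_assignment$home_type,
                                 truth$marker_assignment$gene)
  gene_home <- marker_home[genes]          # NA for non-markers
  mid_rate <- (cfg$motif_rate_high + cfg$motif_rate_low) / 2

  win_start <- pmax(0L, annotation$tss - flank)
  win_end <- annotation$tss + flank

  with_local_seed(derive_seed(cfg$seed, 4L), {
    out <- vector("list", nrow(truth$tf_role))
    for (i in seq_len(nrow(truth$tf_role))) {
      tf <- truth$tf_role$tf[i]
      role <- truth$tf_role$role[i]
      rates <- rep(mid_rate, length(genes))
      if (role != "neutral") {
        own <- !is.na(gene_home) & gene_home == truth$tf_role$home_type[i]
        other <- !is.na(gene_home) & !own
        if (role == "safeguard") {
          rates[own] <- cfg$motif_rate_low
          rates[other] <- cfg$motif_rate_high
        } else {
          rates[own] <- cfg$motif_rate_high
          rates[other] <- cfg$motif_rate_low
        }
      }
      k <- stats::rpois(length(genes), rates)
      tot <- sum(k)
      if (tot == 0L) next
      gi <- rep(seq_along(genes), k)
      lo <- win_start[gi]
      hi <- win_end[gi] - motif_width
      start <- lo + floor(stats::runif(tot) * (hi - lo + 1L))
      out[[i]] <- data.frame(tf = tf, chrom = annotation$chrom[gi],
                             start = as.integer(start),
                             end = as.integer(start + motif_width),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
}

#' Simulate aged-atlas and developmental expression series
#'
#' The aged atlas redraws counts from the young mean structure with every
#' TF's baseline scaled by `aged_fraction` (scalar, or a named per-TF
#' vector; unnamed TFs keep fraction 1). The developmental table places
#' each `lifelong_tfs` member in the top expression quartile of all TFs in
#' exactly `round(persistence * n_samples)` of the
#' `n_timepoints * n_replicates` samples, and well below it elsewhere.
#'
#' @param truth a [plant_truth()] object.
#' @param cfg the [sim_config()].
#' @param aged_fraction fraction of young mean TF expression retained in
#'   the aged atlas.
#' @param lifelong_tfs TFs planted as lifelong-expressed in development
#'   (default: all planted safeguards).
#' @param persistence fraction of developmental samples in which a
#'   lifelong TF sits in the top quartile.
#' @param n_timepoints,n_replicates developmental series layout.
#' @return list with `aged` (a raw [cell_atlas()]) and `dev`
#'   (TF x sample matrix, columns `tXX_rY`).
#' @export
simulate_aging_and_dev_series <- function(truth, cfg, aged_fraction = 1.0,
                                          lifelong_tfs = NULL,
                                          persistence = 0.8,
                                          n_timepoints = 10L,
                                          n_replicates = 2L) {
  validate_sim_config(cfg)
  ids <- sim_ids(cfg)
  if (is.null(lifelong_tfs))
    lifelong_tfs <- truth$tf_role$tf[truth$tf_role$role == "safeguard"]
  frac <- stats::setNames(rep(1, cfg$n_tfs), ids$tfs)
  if (is.null(names(aged_fraction))) frac[] <- aged_fraction
  else frac[names(aged_fraction)] <- aged_fraction

  mm <- sim_mu_matrix(cfg, truth, tf_scale = frac)
  aged_counts <- with_local_seed(derive_seed(cfg$seed, 5L),
                                 rnbinom_matrix(mm$mu, cfg$noise_dispersion))
  colnames(aged_counts) <- sprintf("aged%04d", seq_len(ncol(aged_counts)))
  aged <- cell_atlas(aged_counts,
                     stats::setNames(mm$labels, colnames(aged_counts)), "raw")

  n_samples <- n_timepoints * n_replicates
  n_high <- round(persistence * n_samples)
  dev <- with_local_seed(derive_seed(cfg$seed, 6L), {
    m <- matrix(stats::rlnorm(cfg$n_tfs * n_samples, 0, 0.5),
                nrow = cfg$n_tfs,
                dimnames = list(ids$tfs,
                                sprintf("t%02d_r%d",
                                        rep(seq_len(n_timepoints),
                                            each = n_replicates),
                                        rep(seq_len(n_replicates),
                                            n_timepoints))))
    for (tf in lifelong_tfs) {
      high_in <- sample(n_samples, n_high)
      for (s in seq_len(n_samples)) {
        others <- m[setdiff(rownames(m), lifelong_tfs), s]
        m[tf, s] <- if (s %in% high_in)
          max(others) * (2 + stats::runif(1)) else min(others) * stats::runif(1) * 0.5
      }
    }
    m
  })
  list(aged = aged, dev = dev)
}

#' Simulate a two-condition reprogramming dataset with latent transduction
#'
#' Cells in the overexpression (`OE`) condition are transduced with
#' probability `transduction_rate`; transduced cells have the designated
#' regulon target genes' mean expression scaled by `repression_factor`
#' before negative-binomial noise. Control cells are never transduced.
#' Transduction status is latent in the expression output and exposed only
#' through the returned truth object.
#'
#' @param truth a [plant_truth()] object.
#' @param cfg the [sim_config()].
#' @param regulon_genes target gene set repressed upon transduction;
#'   default samples 100 genes.
#' @param cells_per_condition cells per condition (default
#'   `cfg$cells_per_type`).
#' @return list with `atlas` (raw [cell_atlas()], labels
#'   `control`/`OE`) and `truth` (input truth with `transduced` and
#'   `regulon` filled in).
#' @export
simulate_reprogramming <- function(truth, cfg, regulon_genes = NULL,
                                   cells_per_condition = NULL) {
  validate_sim_config(cfg)
  ids <- sim_ids(cfg)
  n <- cells_per_condition %||% cfg$cells_per_type
  base <- sim_base_means(cfg)
  with_local_seed(derive_seed(cfg$seed, 7L), {
    if (is.null(regulon_genes))
      regulon_genes <- sort(sample(ids$genes, min(100L, cfg$n_genes)))
    cells <- c(sprintf("ctrl%04d", seq_len(n)), sprintf("oe%04d", seq_len(n)))
    condition <- stats::setNames(factor(rep(c("control", "OE"), each = n),
                                        levels = c("control", "OE")), cells)
    transduced <- stats::setNames(rep(FALSE, 2L * n), cells)
    transduced[condition == "OE"] <-
      stats::runif(n) < cfg$transduction_rate
    mu <- matrix(base, nrow = length(base), ncol = 2L * n,
                 dimnames = list(names(base), cells))
    mu[regulon_genes, transduced] <-
      mu[regulon_genes, transduced] * cfg$repression_factor
    counts <- rnbinom_matrix(mu, cfg$noise_dispersion)
    truth$transduced <- transduced
    truth$regulon <- regulon_genes
    list(atlas = cell_atlas(counts, condition, "raw"), truth = truth)
  })
}

#' Simulate peak, DE and accessibility evidence for the planted regulon
#'
#' Emits the file inputs of the regulon/activity pipeline, consistent with
#' the planted truth: a binding peak and an 11-base TF motif hit at every
#' regulon-gene TSS, a differential-expression table in which regulon
#' genes are significantly down under overexpression
#' (log2FC = log2(repression_factor)), and a promoter-accessibility table
#' (control vs OE) in which regulon promoters close (log2FC = 2). Decoy
#' genes carry peak and motif evidence but no significant expression
#' response, so they must not enter the regulon.
#'
#' @param truth a [plant_truth()] with `regulon` set by
#'   [simulate_reprogramming()].
#' @param annotation TSS table covering all genes.
#' @param cfg the [sim_config()].
#' @param tf id of the overexpressed TF (default the first safeguard).
#' @param n_decoy number of decoy peak genes.
#' @return list(peaks, motif_hits, de_table, accessibility_table).
#' @export
simulate_regulon_evidence <- function(truth, annotation, cfg, tf = NULL,
                                      n_decoy = 50L) {
  if (is.null(truth$regulon))
    stop_input("truth carries no regulon; run simulate_reprogramming first")
  if (is.null(tf))
    tf <- truth$tf_role$tf[truth$tf_role$role == "safeguard"][1L]
  genes <- annotation$gene
  missing <- setdiff(truth$regulon, genes)
  if (length(missing))
    stop_data("annotation missing regulon gene(s): %s",
              paste(utils::head(missing, 5L), collapse = ", "))
  decoys <- with_local_seed(derive_seed(cfg$seed, 8L),
                            sample(setdiff(genes, truth$regulon),
                                   min(n_decoy,
                                       length(genes) - length(truth$regulon))))
  evidence_genes <- c(truth$regulon, decoys)
  idx <- match(evidence_genes, annotation$gene)
  peaks <- data.frame(chrom = annotation$chrom[idx],
                      start = pmax(0L, annotation$tss[idx] - 150L),
                      end = annotation$tss[idx] + 150L,
                      name = paste0("peak_", evidence_genes),
                      stringsAsFactors = FALSE)
  motif_hits <- data.frame(tf = tf, chrom = annotation$chrom[idx],
                           start = pmax(0L, annotation$tss[idx] - 5L),
                           end = annotation$tss[idx] + 6L,
                           stringsAsFactors = FALSE)
  is_reg <- genes %in% truth$regulon
  is_decoy <- genes %in% decoys
  de <- data.frame(gene = genes,
                   log2_fc = ifelse(is_reg, log2(cfg$repression_factor), 0),
                   p_adj = ifelse(is_reg, 1e-6, 1),
                   stringsAsFactors = FALSE)
  de$log2_fc[is_decoy] <- -0.5
  de$p_adj[is_decoy] <- 0.5
  acc <- data.frame(gene = genes,
                    log2_fc = ifelse(is_reg, 2, 0),
                    stringsAsFactors = FALSE)
  list(peaks = peaks, motif_hits = motif_hits, de_table = de,
       accessibility_table = acc)
}
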