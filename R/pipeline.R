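# Pipeline orchestration: the safeguard screen
# (normalize -> markers -> dedup -> promoters -> densities -> z-scores ->
# score -> lifelong filters -> shortlist) and the reprogramming activity
# analysis (regulon -> module scores -> activity -> transduction filter ->
# correlations), plus JSON run manifests for reproducibility.

#' Run the safeguard-repressor screen in memory
#'
#' @param atlas a raw or normalized [cell_atlas()] containing gene and TF
#'   rows.
#' @param tf_ids rows of `atlas` treated as transcription factors.
#' @param motif_hits motif-hit table (tf, chrom, start, end).
#' @param annotation TSS table (gene, chrom, tss).
#' @param n_top signature size per cell type (default 1000).
#' @param flank promoter half-width (default 2 kb).
#' @param zscore_axis passed to [zscore_across_celltypes()].
#' @param zmax passed to [safeguard_scores()].
#' @param aged optional aged [cell_atlas()] for the lifelong-aged filter.
#' @param dev_table optional TF x sample developmental matrix for the
#'   lifelong-developmental filter.
#' @param top_k shortlist size per cell type.
#' @param require_lifelong restrict the shortlist to lifelong TFs.
#' @return list(score_table, shortlist, z_expr, z_motif, scores,
#'   signatures, density).
#' @export
screen_safeguards <- function(atlas, tf_ids, motif_hits, annotation,
                              n_top = 1000L, flank = 2000L,
                              zscore_axis = "tf", zmax = "abs",
                              aged = NULL, dev_table = NULL, top_k = 3L,
                              require_lifelong = FALSE) {
  if (atlas$normalization == "raw") atlas <- median_normalize_cpm(atlas)
  missing <- setdiff(tf_ids, rownames(atlas$counts))
  if (length(missing))
    stop_input("TF(s) absent from atlas: %s",
               paste(utils::head(missing, 5L), collapse = ", "))
  genes <- setdiff(rownames(atlas$counts), tf_ids)
  sigs <- deduplicate_signatures(build_signatures(atlas, n_top = n_top,
                                                  genes = genes))
  windows <- make_promoter_windows(annotation, flank = flank)
  occ <- count_motif_hits(motif_hits, windows)
  occ <- occ[tf_ids[tf_ids %in% rownames(occ)], , drop = FALSE]
  dens <- mean_motif_density(occ, sigs)

  mean_expr <- celltype_means(atlas, tf_ids)
  z_expr <- zscore_across_celltypes(mean_expr, axis = zscore_axis)
  dens_full <- matrix(0, nrow = length(tf_ids), ncol = ncol(dens),
                      dimnames = list(tf_ids, colnames(dens)))
  dens_full[rownames(dens), ] <- dens
  z_motif <- zscore_across_celltypes(dens_full, axis = zscore_axis)
  scores <- safeguard_scores(z_expr, z_motif, zmax = zmax)

  lifelong_aged <- lifelong_dev <- NULL
  if (!is.null(aged)) {
    if (aged$normalization == "raw") aged <- median_normalize_cpm(aged)
    home <- colnames(mean_expr)[max.col(mean_expr)]
    lifelong_aged <- stats::setNames(vapply(seq_along(tf_ids), function(i)
      lifelong_aged_filter(atlas, aged, tf_ids[i], home[i]), logical(1)),
      tf_ids)
  }
  if (!is.null(dev_table))
    lifelong_dev <- stats::setNames(vapply(tf_ids, function(tf)
      lifelong_dev_filter(dev_table, tf), logical(1)), tf_ids)

  tab <- safeguard_score_table(mean_expr, z_expr, z_motif, scores,
                               lifelong_aged, lifelong_dev)
  list(score_table = tab,
       shortlist = shortlist(tab, top_k = top_k,
                             require_lifelong = require_lifelong),
       z_expr = z_expr, z_motif = z_motif, scores = scores,
       signatures = sigs, density = dens_full)
}

#' Run the reprogramming activity analysis in memory
#'
#' @param atlas a [cell_atlas()] whose labels are the condition
#'   (`control` / `OE`).
#' @param regulon a [build_regulon()] object (or target gene vector).
#' @param identity_sets named list of identity gene sets for module
#'   scoring.
#' @param mode activity mode (`"repressor"` default).
#' @param rule transduction-filter rule.
#' @param n_bins,n_ctrl,seed module-score parameters.
#' @return list(activity_frame, correlations, identity_scores).
#' @export
run_activity_analysis <- function(atlas, regulon, identity_sets = list(),
                                  mode = "repressor",
                                  rule = "as_published", n_bins = 24L,
                                  n_ctrl = 100L, seed = 1L) {
  if (atlas$normalization == "raw") atlas <- median_normalize_cpm(atlas)
  act <- tf_activity(atlas, regulon, mode = mode, n_bins = n_bins,
                     n_ctrl = n_ctrl, seed = seed)
  frame <- filter_untransduced(act, atlas$labels, rule = rule)
  id_scores <- NULL; cors <- NULL
  if (length(identity_sets)) {
    id_scores <- vapply(identity_sets, function(gs)
      module_score(atlas, gs, n_bins = n_bins, n_ctrl = n_ctrl,
                   seed = seed),
      numeric(ncol(atlas$counts)))
    cors <- identity_activity_correlation(id_scores, act,
                                          kept = frame$kept)
    for (s in names(cors)) frame[[paste0("score_", s)]] <- id_scores[, s]
  }
  list(activity_frame = frame, correlations = cors,
       identity_scores = id_scores)
}

run_manifest <- function(inputs, config, seed, counts) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  list(inputs = digests, config = config, seed = seed,
       version = as.character(utils::packageVersion("safeguardR")),
       row_counts = counts)
}

#' Run the file-based screen pipeline
#'
#' Reads expression + labels, motif BED and TSS TSV named in `config`,
#' runs [screen_safeguards()], and writes `score_table.tsv`,
#' `shortlist.tsv` and `manifest.json` to `out_dir`.
#'
#' @param config named list (or YAML/JSON path) with fields
#'   `expression` (dir or TSV), `expression_format`, `labels`,
#'   `motif_bed`, `tss`, `tf_ids` (vector or file of ids), and optional
#'   `n_top`, `flank`, `top_k`, `zscore_axis`, `zmax`, `seed`.
#' @param out_dir output directory.
#' @return Invisibly, the [screen_safeguards()] result plus `manifest`.
#' @export
run_screen <- function(config, out_dir) {
  config <- resolve_config(config)
  for (f in c("expression", "labels", "motif_bed", "tss"))
    if (is.null(config[[f]]))
      stop_input("screen config missing field: %s", f)
  for (f in c("labels", "motif_bed", "tss"))
    if (!file.exists(config[[f]]))
      stop_data("missing input file: %s", config[[f]])
  atlas <- read_expression(config$expression,
                           config$expression_format %||% "mtx_triplet",
                           config$labels)
  hits <- read_bed(config$motif_bed)
  hits$tf <- hits$name
  annotation <- read_tss(config$tss)
  tf_ids <- config$tf_ids
  if (length(tf_ids) == 1L && file.exists(tf_ids))
    tf_ids <- readLines(tf_ids)
  if (is.null(tf_ids))
    tf_ids <- intersect(unique(hits$tf), rownames(atlas$counts))

  res <- screen_safeguards(atlas, tf_ids, hits, annotation,
                           n_top = config$n_top %||% 1000L,
                           flank = config$flank %||% 2000L,
                           zscore_axis = config$zscore_axis %||% "tf",
                           zmax = config$zmax %||% "abs",
                           top_k = config$top_k %||% 3L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_score_table <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_score_table(res$score_table, file.path(out_dir, "score_table.tsv"))
  write_score_table(res$shortlist, file.path(out_dir, "shortlist.tsv"))
  res$manifest <- run_manifest(
    config[c("labels", "motif_bed", "tss")], config,
    config$seed %||% NA,
    list(score_table = nrow(res$score_table),
         shortlist = nrow(res$shortlist),
         signature_genes = sum(vapply(res$signatures, nrow, 1L))))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(res)
}

#' Run the file-based activity pipeline
#'
#' Reads the reprogramming expression + condition labels, peak and motif
#' BEDs, DE and accessibility TSVs and optional identity-set GMT named in
#' `config`; builds the regulon, scores activity, applies the
#' transduction filter and writes `activity.tsv`, `regulon.json` and
#' `manifest.json`.
#'
#' @param config named list (or YAML/JSON path) with fields `expression`,
#'   `expression_format`, `labels`, `peaks_bed`, `motif_bed`, `tss`,
#'   `de_table`, `tf`, `contrast`, and optional `accessibility_table`,
#'   `identity_gmt`, `rule`, `mode`, `de_alpha`, `atac_lfc_threshold`,
#'   `tss_window`, `n_bins`, `n_ctrl`, `seed`.
#' @param out_dir output directory.
#' @return Invisibly, the analysis result plus `regulon` and `manifest`.
#' @export
run_activity <- function(config, out_dir) {
  config <- resolve_config(config)
  for (f in c("expression", "labels", "peaks_bed", "motif_bed", "tss",
              "de_table", "tf", "contrast"))
    if (is.null(config[[f]]))
      stop_input("activity config missing field: %s", f)
  atlas <- read_expression(config$expression,
                           config$expression_format %||% "mtx_triplet",
                           config$labels)
  peaks <- read_bed(config$peaks_bed)
  motifs <- read_bed(config$motif_bed)
  annotation <- read_tss(config$tss)
  de <- read_de_table(config$de_table)
  acc <- if (!is.null(config$accessibility_table))
    read_de_table(config$accessibility_table) else NULL

  supported <- intersect_peaks_with_motifs(peaks, motifs,
                                           config$motif_width_pad %||% 50L)
  pg <- annotate_peaks_to_genes(supported, annotation,
                                window = config$tss_window %||% 1000L)
  reg <- build_regulon(config$tf, pg, de, acc,
                       de_alpha = config$de_alpha %||% 0.05,
                       atac_lfc_threshold = config$atac_lfc_threshold %||% 1,
                       contrast = config$contrast)
  sets <- if (!is.null(config$identity_gmt)) read_gmt(config$identity_gmt)
  else list()
  res <- run_activity_analysis(atlas, reg, sets,
                               mode = config$mode %||% "repressor",
                               rule = config$rule %||% "as_published",
                               n_bins = config$n_bins %||% 24L,
                               n_ctrl = config$n_ctrl %||% 100L,
                               seed = config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$activity_frame, file.path(out_dir, "activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(reg), file.path(out_dir, "regulon.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$regulon <- reg
  res$manifest <- run_manifest(
    config[c("labels", "peaks_bed", "motif_bed", "tss", "de_table")],
    config, config$seed %||% 1L,
    list(activity = nrow(res$activity_frame),
         regulon_targets = nrow(reg$targets),
         high_confidence = length(reg$high_confidence)))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(res)
}

#' Write a full synthetic input bundle to disk
#'
#' Materializes everything the file-based pipelines consume: the atlas
#' (MTX triplet + labels), motif hits (BED), TSS table (TSV), planted
#' truth (JSON), aged atlas, developmental table, and the reprogramming
#' dataset with its DE/accessibility tables and peak BED.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list of the generated in-memory objects.
#' @export
write_sim_inputs <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_atlas(cfg)
  annotation <- make_tss_annotation(rownames(sim$atlas$counts))
  hits <- simulate_motif_hits(sim$truth, annotation, cfg)
  series <- simulate_aging_and_dev_series(sim$truth, cfg)
  rep <- simulate_reprogramming(sim$truth, cfg)
  evidence <- simulate_regulon_evidence(rep$truth, annotation, cfg)

  write_expression(sim$atlas, file.path(out_dir, "atlas"))
  write_expression(series$aged, file.path(out_dir, "aged"))
  write_expression(rep$atlas, file.path(out_dir, "reprogramming"))
  write_bed(hits, file.path(out_dir, "motif_hits.bed"))
  write_bed(evidence$peaks, file.path(out_dir, "peaks.bed"))
  write_bed(evidence$motif_hits, file.path(out_dir, "regulon_motifs.bed"))
  utils::write.table(evidence$de_table, file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(evidence$accessibility_table,
                     file.path(out_dir, "accessibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tss(annotation, file.path(out_dir, "tss.tsv"))
  write_truth_json(rep$truth, file.path(out_dir, "truth.json"))
  utils::write.table(data.frame(tf = rownames(series$dev), series$dev,
                                check.names = FALSE),
                     file.path(out_dir, "dev_series.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim_ids(cfg)$tfs, file.path(out_dir, "tf_ids.txt"))
  invisible(list(sim = sim, annotation = annotation, hits = hits,
                 series = series, reprogramming = rep,
                 evidence = evidence))
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  config
}
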