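# Promoter windows, motif-hit counting and per-signature mean motif
# density. All intervals are 0-based half-open; a hit belongs to a window
# iff its midpoint lies inside (a documented choice that prevents double
# counting at window edges, though a hit whose midpoint falls in two
# overlapping gene windows is counted once for each gene).

#' Symmetric promoter windows around TSSs
#'
#' @param annotation data.frame (gene, chrom, tss, strand).
#' @param flank half-width in bases (default 2 kb, the screen's promoter
#'   definition); windows are `[max(0, tss - flank), tss + flank)` and
#'   strand-independent.
#' @return data.frame (gene, chrom, start, end).
#' @export
make_promoter_windows <- function(annotation, flank = 2000L) {
  if (flank <= 0) stop_input("flank must be > 0")
  if (anyDuplicated(annotation$gene))
    stop_data("annotation has duplicate gene ids")
  data.frame(gene = annotation$gene, chrom = annotation$chrom,
             start = pmax(0L, as.integer(annotation$tss - flank)),
             end = as.integer(annotation$tss + flank),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(df, what = "interval") {
  bad <- which(!(df$start < df$end) | df$start < 0 |
                 is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop_data("malformed %s at row(s): %s", what,
              paste(utils::head(bad, 5L), collapse = ", "))
  invisible(df)
}

# Integer point such that 'midpoint in [start, end)' over real midpoints
# is equivalent to 'floor(midpoint) in [start, end)' over integers.
interval_midpoint <- function(start, end) floor((start + end) / 2)

#' Count motif hits per TF per gene promoter
#'
#' A hit is attributed to a gene iff the hit's midpoint lies inside the
#' gene's promoter window (half-open). A hit whose midpoint falls in
#' several overlapping windows counts once for each gene.
#'
#' @param hits data.frame (tf, chrom, start, end), 0-based half-open.
#' @param windows promoter windows from [make_promoter_windows()].
#' @return integer matrix, TF x gene, covering every window gene.
#' @export
count_motif_hits <- function(hits, windows) {
  validate_intervals(hits, "motif hit")
  validate_intervals(windows, "promoter window")
  tfs <- sort(unique(hits$tf))
  occ <- matrix(0L, nrow = length(tfs), ncol = nrow(windows),
                dimnames = list(tfs, windows$gene))
  if (!nrow(hits)) return(occ)
  mid <- interval_midpoint(hits$start, hits$end)
  pts <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  ov <- GenomicRanges::findOverlaps(pts, win)
  if (length(ov)) {
    tf_idx <- match(hits$tf[S4Vectors::queryHits(ov)], tfs)
    tab <- table(factor(tf_idx, levels = seq_along(tfs)),
                 factor(S4Vectors::subjectHits(ov),
                        levels = seq_len(nrow(windows))))
    occ[] <- occ + as.integer(tab)
  }
  occ
}

#' Mean motif density per TF per cell-type signature
#'
#' Arithmetic mean of promoter hit counts over the (deduplicated)
#' signature genes of each cell type.
#'
#' @param occ TF x gene count matrix from [count_motif_hits()].
#' @param signatures a deduplicated `signature_table`.
#' @return numeric matrix, TF x cell type. An empty signature yields
#'   density 0 for every TF, with a warning.
#' @export
mean_motif_density <- function(occ, signatures) {
  dens <- matrix(0, nrow = nrow(occ), ncol = length(signatures),
                 dimnames = list(rownames(occ), names(signatures)))
  for (ct in names(signatures)) {
    genes <- signatures[[ct]]$gene
    if (!length(genes)) {
      warning(sprintf("empty signature for %s; density set to 0", ct))
      next
    }
    missing <- setdiff(genes, colnames(occ))
    if (length(missing))
      stop_input("signature gene(s) absent from occurrence matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
    dens[, ct] <- rowMeans(occ[, genes, drop = FALSE])
  }
  dens
}
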