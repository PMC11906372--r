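# Regulon construction from binding-peak, motif and differential-expression
# evidence: peaks are filtered for motif support, annotated to genes by TSS
# proximity, and intersected with a differential-expression response; a
# high-confidence repressed subset additionally requires promoter closing
# in differential accessibility.

#' Annotate peaks to genes by TSS proximity
#'
#' A peak maps to a gene iff the peak interval overlaps
#' `[TSS - window, TSS + window)` by at least one base (half-open
#' intersection). One peak may map to several genes.
#'
#' @param peaks data.frame (chrom, start, end), 0-based half-open;
#'   optional `name` column used as peak id (default `chrom:start-end`).
#' @param annotation TSS table (gene, chrom, tss).
#' @param window TSS half-width in bases (default 1 kb).
#' @return data.frame (peak, gene), one row per assignment.
#' @export
annotate_peaks_to_genes <- function(peaks, annotation, window = 1000L) {
  if (window <= 0) stop_input("window must be > 0")
  validate_intervals(peaks, "peak")
  ids <- if (!is.null(peaks$name)) peaks$name
  else sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  if (!nrow(peaks))
    return(data.frame(peak = character(), gene = character()))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  win <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(pmax(0L, annotation$tss -
                                                        window) + 1L,
                                                 annotation$tss + window))
  ov <- GenomicRanges::findOverlaps(pk, win)
  data.frame(peak = ids[S4Vectors::queryHits(ov)],
             gene = annotation$gene[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Filter peaks for motif support
#'
#' Each motif hit is symmetrically extended to a total width of
#' `motif_width_pad` bases (left pad `floor((pad - len) / 2)`, remainder on
#' the right); peaks are retained iff they overlap at least one extended
#' motif interval.
#'
#' @param peaks data.frame (chrom, start, end), 0-based half-open.
#' @param motif_hits data.frame (chrom, start, end).
#' @param motif_width_pad total extended width in bases (default 50).
#' @return The subset of `peaks` with motif support, original order.
#' @export
intersect_peaks_with_motifs <- function(peaks, motif_hits,
                                        motif_width_pad = 50L) {
  validate_intervals(peaks, "peak")
  if (!nrow(motif_hits)) return(peaks[0, , drop = FALSE])
  validate_intervals(motif_hits, "motif hit")
  len <- motif_hits$end - motif_hits$start
  pad_left <- pmax(0L, floor((motif_width_pad - len) / 2))
  pad_right <- pmax(0L, motif_width_pad - len - pad_left)
  ext_start <- pmax(0L, motif_hits$start - pad_left)
  ext_end <- motif_hits$end + pad_right
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  mh <- GenomicRanges::GRanges(motif_hits$chrom,
                               IRanges::IRanges(ext_start + 1L, ext_end))
  keep <- IRanges::overlapsAny(pk, mh)
  peaks[keep, , drop = FALSE]
}

#' Build a TF regulon from peak, motif and expression evidence
#'
#' Targets are genes carrying a motif-supported binding peak near their TSS
#' (the `peak_gene_map`, typically from [intersect_peaks_with_motifs()]
#' followed by [annotate_peaks_to_genes()]) whose differential expression
#' under the declared contrast is significant at `de_alpha`. Direction is
#' `repressed` iff expression falls under TF gain. The high-confidence
#' repressed subset additionally requires the promoter to close in
#' accessibility: control-vs-OE log2 fold change above
#' `atac_lfc_threshold`.
#'
#' @param tf TF id.
#' @param peak_gene_map data.frame (peak, gene) from
#'   [annotate_peaks_to_genes()].
#' @param de_table data.frame (gene, log2_fc, p_adj) of the expression
#'   contrast.
#' @param accessibility_table optional data.frame (gene, log2_fc) of
#'   promoter accessibility, control vs OE (positive = closed upon OE).
#' @param de_alpha adjusted-p cutoff (default 0.05).
#' @param atac_lfc_threshold promoter-closing cutoff (default 1).
#' @param contrast orientation of `de_table`'s fold changes:
#'   `"oe_vs_control"` (negative log2FC = repressed under TF gain,
#'   default) or `"control_vs_oe"`.
#' @return An object of class `regulon`: list(tf, targets, high_confidence)
#'   where `targets` is a data.frame (gene, direction, log2_fc, p_adj,
#'   promoter_closed).
#' @export
build_regulon <- function(tf, peak_gene_map, de_table,
                          accessibility_table = NULL, de_alpha = 0.05,
                          atac_lfc_threshold = 1,
                          contrast = c("oe_vs_control", "control_vs_oe")) {
  contrast <- match.arg(contrast)
  genes <- unique(peak_gene_map$gene)
  hit <- match(genes, de_table$gene)
  if (anyNA(hit)) {
    warning(sprintf("%d peak-associated gene(s) absent from DE table; skipped",
                    sum(is.na(hit))))
    genes <- genes[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  lfc <- de_table$log2_fc[hit]
  if (contrast == "control_vs_oe") lfc <- -lfc
  padj <- de_table$p_adj[hit]
  keep <- !is.na(padj) & padj < de_alpha
  genes <- genes[keep]; lfc <- lfc[keep]; padj <- padj[keep]
  direction <- ifelse(lfc < 0, "repressed", "activated")
  closed <- rep(NA, length(genes))
  if (!is.null(accessibility_table)) {
    am <- match(genes, accessibility_table$gene)
    closed <- !is.na(am) &
      accessibility_table$log2_fc[am] > atac_lfc_threshold
  }
  targets <- data.frame(gene = genes, direction = direction, log2_fc = lfc,
                        p_adj = padj, promoter_closed = closed,
                        stringsAsFactors = FALSE)
  structure(list(tf = tf, targets = targets,
                 high_confidence = genes[direction == "repressed" &
                                           closed %in% TRUE]),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon of %s: %d target(s) (%d repressed, %d activated), %d high-confidence repressed\n",
              x$tf, nrow(x$targets), sum(x$targets$direction == "repressed"),
              sum(x$targets$direction == "activated"),
              length(x$high_confidence)))
  invisible(x)
}
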