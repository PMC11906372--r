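# Cell-type signature derivation: one-vs-rest one-sided Wilcoxon rank-sum
# per gene, Benjamini-Hochberg correction within each comparison, ranking
# by adjusted p (ties: effect size, then gene id), and pairwise overlap
# removal across cell types.

# Per-gene rank statistics shared by every one-vs-rest comparison on the
# same matrix: within-row ranks (average on ties) and the tie-correction
# term sum(t^3 - t).
row_rank_stats <- function(mat) {
  ranks <- t(apply(mat, 1L, rank))
  tie_term <- apply(mat, 1L, function(x) {
    t <- rle(sort(x))$lengths
    sum(t^3 - t)
  })
  list(ranks = ranks, tie_term = tie_term)
}

# One-sided (greater) Wilcoxon rank-sum p-values for every row of `mat`,
# comparing columns in `in_group` against the rest. Exact (stats::pwilcox)
# when the pooled sample is small and tie-free; otherwise the tie-corrected
# normal approximation with continuity correction, vectorised across genes.
rowwise_wilcox_greater <- function(mat, in_group, exact_max_n = 20L,
                                   rank_stats = NULL) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  if (is.null(rank_stats)) rank_stats <- row_rank_stats(mat)
  W <- rowSums(rank_stats$ranks[, in_group, drop = FALSE]) -
    n1 * (n1 + 1) / 2
  tie_term <- rank_stats$tie_term
  has_ties <- tie_term > 0

  p <- numeric(nrow(mat))
  use_exact <- (n <= exact_max_n) & !has_ties
  if (any(use_exact))
    p[use_exact] <- stats::pwilcox(W[use_exact] - 1, n1, n2,
                                   lower.tail = FALSE)
  if (any(!use_exact)) {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term[!use_exact] /
                                    (n * (n - 1))))
    z <- (W[!use_exact] - mu - 0.5) / sigma     # continuity correction
    z[sigma == 0] <- 0
    p[!use_exact] <- stats::pnorm(z, lower.tail = FALSE)
  }
  p
}

#' Rank cell-type-enriched genes (one-vs-rest)
#'
#' Tests every gene for enrichment in `cell_type` against all other cells
#' with a one-sided Wilcoxon rank-sum test, adjusts p-values with
#' Benjamini-Hochberg, and returns the top `n_top` genes ranked by adjusted
#' p ascending, ties broken by log2 fold change descending and then gene id.
#' The effect size is the log2 ratio of group means with pseudocount 1.
#'
#' @param atlas a normalized [cell_atlas()].
#' @param cell_type a label present in the atlas with at least 2 cells.
#' @param n_top signature size cap (the reference screen used 1,000).
#' @param genes optional subset of rows to consider (default all).
#' @param rank_stats precomputed [row_rank_stats()] of the considered
#'   rows, reused across cell types by [build_signatures()].
#' @return data.frame (gene, log2_fc, p_value, p_adj, rank).
#' @export
rank_markers <- function(atlas, cell_type, n_top = 1000L, genes = NULL,
                         rank_stats = NULL) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (!cell_type %in% levels(atlas$labels))
    stop_input("unknown cell type: %s", cell_type)
  if (n_top < 1L) stop_input("n_top must be >= 1")
  in_group <- atlas$labels == cell_type
  if (sum(in_group) < 2L)
    stop_input("cell type %s has fewer than 2 cells", cell_type)
  mat <- atlas$counts
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]

  p <- rowwise_wilcox_greater(mat, in_group, rank_stats = rank_stats)
  lfc <- log2((rowMeans(mat[, in_group, drop = FALSE]) + 1) /
                (rowMeans(mat[, !in_group, drop = FALSE]) + 1))
  padj <- stats::p.adjust(p, method = "BH")
  ord <- order(padj, -lfc, rownames(mat))
  keep <- utils::head(ord, n_top)
  data.frame(gene = rownames(mat)[keep], log2_fc = lfc[keep],
             p_value = p[keep], p_adj = padj[keep],
             rank = seq_along(keep), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build signatures for every cell type
#'
#' @inheritParams rank_markers
#' @return Named list of [rank_markers()] tables, class `signature_table`.
#' @export
build_signatures <- function(atlas, n_top = 1000L, genes = NULL) {
  stopifnot(inherits(atlas, "cell_atlas"))
  mat <- atlas$counts
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  rs <- row_rank_stats(mat)
  out <- lapply(levels(atlas$labels), rank_markers, atlas = atlas,
                n_top = n_top, genes = genes, rank_stats = rs)
  names(out) <- levels(atlas$labels)
  structure(out, class = "signature_table")
}

#' Remove genes shared between cell-type signatures
#'
#' Any gene appearing in two or more signatures is removed from all of
#' them, making the signatures pairwise disjoint. Within-type order and
#' original ranks are preserved.
#'
#' @param signatures a `signature_table` from [build_signatures()].
#' @return The deduplicated `signature_table`.
#' @export
deduplicate_signatures <- function(signatures) {
  all_genes <- unlist(lapply(signatures, `[[`, "gene"), use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  out <- lapply(signatures, function(df)
    df[!df$gene %in% dup, , drop = FALSE])
  structure(out, class = "signature_table")
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("signature_table: %d cell types, %s genes each\n",
              length(x), paste(range(vapply(x, nrow, 1L)), collapse = "-")))
  invisible(x)
}
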