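#' Labeled cell-by-gene expression atlas
#'
#' Lightweight container for a gene x cell expression matrix with one
#' cell-type label per cell and an explicit normalization state. All
#' downstream scoring operates on objects of this class.
#'
#' @param counts numeric matrix, genes in rows (unique rownames required),
#'   cells in columns (unique colnames required); no negative entries.
#' @param labels character or factor of cell-type labels, either named by
#'   cell or in column order of `counts`.
#' @param normalization `"raw"` for raw counts or `"median_cpm"` after
#'   [median_normalize_cpm()].
#'
#' @return An object of class `cell_atlas`: a list with elements `counts`,
#'   `labels` (named factor) and `normalization`.
#' @export
cell_atlas <- function(counts, labels, normalization = c("raw", "median_cpm")) {
  normalization <- match.arg(normalization)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_data("atlas gene ids must be present and unique")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_data("atlas cell ids must be present and unique")
  if (any(counts < 0))
    stop_data("atlas contains negative expression values")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(counts), names(labels))
    if (length(missing))
      stop_data("labels missing for cell(s): %s",
                paste(utils::head(missing, 5L), collapse = ", "))
    labels <- labels[colnames(counts)]
  } else if (length(labels) != ncol(counts)) {
    stop_data("got %d labels for %d cells", length(labels), ncol(counts))
  }
  labels <- factor(as.character(labels))
  names(labels) <- colnames(counts)
  structure(list(counts = counts, labels = labels,
                 normalization = normalization),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("cell_atlas: %d genes x %d cells, %d cell type(s), %s\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$labels),
              x$normalization))
  invisible(x)
}

#' @export
dim.cell_atlas <- function(x) dim(x$counts)

#' Median-library-size CPM normalization
#'
#' Scales each cell so that all cells have the library size of the median
#' cell: cell j is multiplied by `median(total counts) / total_j`. This is
#' counts-per-million up to one global constant, and every downstream
#' z-score is invariant to that constant.
#'
#' @param atlas a raw-counts [cell_atlas()].
#' @return The atlas with normalized values and `normalization`
#'   set to `"median_cpm"`. Gene and cell order are preserved.
#' @export
median_normalize_cpm <- function(atlas) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (atlas$normalization != "raw")
    stop_input("atlas is already normalized (%s)", atlas$normalization)
  totals <- colSums(atlas$counts)
  if (any(totals == 0)) {
    bad <- colnames(atlas$counts)[totals == 0]
    stop_data("cell(s) with zero total count: %s",
              paste(utils::head(bad, 5L), collapse = ", "))
  }
  scale <- stats::median(totals) / totals
  atlas$counts <- sweep(atlas$counts, 2L, scale, `*`)
  atlas$normalization <- "median_cpm"
  atlas
}

#' Mean expression per cell type
#'
#' @param atlas a [cell_atlas()].
#' @param genes optional subset of row ids (default all rows).
#' @return numeric matrix, genes x cell types.
#' @export
celltype_means <- function(atlas, genes = NULL) {
  stopifnot(inherits(atlas, "cell_atlas"))
  m <- atlas$counts
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop_input("gene(s) absent from atlas: %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  types <- levels(atlas$labels)
  out <- vapply(types, function(ct)
    rowMeans(m[, atlas$labels == ct, drop = FALSE]),
    numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), types))
}
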