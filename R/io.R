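# Readers and writers for the pipeline's plain-text interchange formats:
# expression matrices (Matrix Market triplet or dense TSV) with label TSVs,
# BED intervals (0-based half-open), TSS tables, GMT gene sets,
# differential tables and JSON truth/regulon/manifest files.

#' Read an expression atlas from disk
#'
#' @param path for `mtx_triplet`, a directory containing `matrix.mtx`
#'   (genes x cells), `genes.tsv` and `barcodes.tsv`; for `dense_tsv`, a
#'   TSV with gene ids in the first column and cells as columns.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @param labels_path two-column TSV (cell, label) covering every cell.
#' @param normalization state of the stored values (default raw counts).
#' @return A [cell_atlas()].
#' @export
read_expression <- function(path, format = c("mtx_triplet", "dense_tsv"),
                            labels_path, normalization = "raw") {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
      if (!file.exists(file.path(path, f)))
        stop_data("missing companion file %s in %s", f, path)
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop_data("matrix is %d x %d but %d gene and %d cell ids given",
                nrow(m), ncol(m), length(genes), length(cells))
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (anyDuplicated(rownames(m)))
    stop_data("duplicate gene id(s) in %s", path)
  if (any(m < 0)) stop_data("negative expression value(s) in %s", path)
  lab <- utils::read.delim(labels_path, header = TRUE,
                           stringsAsFactors = FALSE)
  labels <- stats::setNames(lab[[2]], lab[[1]])
  cell_atlas(m, labels, normalization)
}

#' Write an expression atlas to disk
#'
#' @param atlas a [cell_atlas()].
#' @param dir output directory (created if needed).
#' @param format `"mtx_triplet"` (matrix.mtx + genes.tsv + barcodes.tsv)
#'   or `"dense_tsv"` (expression.tsv).
#' @return Invisibly, the paths written (labels.tsv always included).
#' @export
write_expression <- function(atlas, dir,
                             format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx_triplet") {
    Matrix::writeMM(methods::as(Matrix::Matrix(atlas$counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(atlas$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(atlas$counts), file.path(dir, "barcodes.tsv"))
    paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(atlas$counts), atlas$counts,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- file.path(dir, "expression.tsv")
  }
  utils::write.table(data.frame(cell = names(atlas$labels),
                                label = as.character(atlas$labels)),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, file.path(dir, "labels.tsv")))
}

#' Read/write 6-column BED (0-based, half-open)
#'
#' The `name` column carries the TF id for motif-hit files and the peak id
#' for peak files.
#'
#' @param path file path.
#' @return data.frame (chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_data("missing BED file: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_data("BED file %s has fewer than 3 columns", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name" else df$name <- "."
  if (ncol(df) >= 5L) names(df)[5] <- "score" else df$score <- 0L
  if (ncol(df) >= 6L) names(df)[6] <- "strand" else df$strand <- "+"
  validate_intervals(df, paste0("BED row in ", basename(path)))
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' @rdname read_bed
#' @param intervals data.frame with columns chrom, start, end and
#'   optionally name (or tf), score, strand.
#' @export
write_bed <- function(intervals, path) {
  name <- intervals$name %||% intervals$tf %||% "."
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, intervals$score %||% 0L,
                    intervals$strand %||% "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a TSS annotation TSV (gene, chrom, tss, strand)
#' @param path file path.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop_data("missing TSS file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss")
  if (!all(need %in% names(df)))
    stop_data("TSS file %s lacks column(s): %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$tss < 0)) stop_data("negative TSS position in %s", path)
  if (anyDuplicated(df$gene)) stop_data("duplicate gene in TSS file %s", path)
  df
}

#' @rdname read_tss
#' @param annotation TSS data.frame.
#' @export
write_tss <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential table (gene, log2_fc, p_adj) from TSV
#'
#' Accepts the column names `gene`, `log2_fc`/`log2fc`/`lfc`, and
#' `p_adj`/`padj` (accessibility tables may omit the p column).
#' @param path file path.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop_data("missing table: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(df)
  lfc <- intersect(c("log2_fc", "log2fc", "lfc"), nm)[1]
  padj <- intersect(c("p_adj", "padj"), nm)[1]
  if (!"gene" %in% nm || is.na(lfc))
    stop_data("table %s needs columns gene and log2_fc", path)
  out <- data.frame(gene = df$gene, log2_fc = df[[lfc]],
                    stringsAsFactors = FALSE)
  if (!is.na(padj)) out$p_adj <- df[[padj]]
  out
}

#' Read/write GMT gene sets
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_data("missing GMT file: %s", path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(s)
    paste(c(s, "na", sets[[s]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write/read planted truth as JSON
#' @param truth a [plant_truth()] object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- unclass(truth)
  # keep cell names on the transduced flags (JSON object, not array)
  if (!is.null(obj$transduced)) obj$transduced <- as.list(obj$transduced)
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$transduced)) x$transduced <- unlist(x$transduced)
  structure(x, class = "planted_truth")
}
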