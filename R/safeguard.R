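# Safeguard-repressor scoring: z-score scaling of TF expression and of
# promoter motif density across cell types, the combined score
# S = Z_expression / max|Z_expression| - Z_motif / max|Z_motif|  (in [-2, 2]),
# lifelong-expression filters against an aged atlas and a developmental
# series, and per-cell-type candidate shortlists.

#' Z-score a TF x cell-type matrix
#'
#' Default axis scales each TF's values across cell types (the
#' specificity reading: a high z marks the cell type where this TF is
#' unusually high). The alternative axis scales within each cell type
#' across TFs. Sample (n-1) standard deviation; zero-variance rows map to
#' all-zero z with a warning.
#'
#' @param values numeric matrix, TF x cell type.
#' @param axis `"tf"` (per TF across cell types, default) or
#'   `"cell_type"`.
#' @return matrix of the same shape.
#' @export
zscore_across_celltypes <- function(values, axis = c("tf", "cell_type")) {
  axis <- match.arg(axis)
  values <- as.matrix(values)
  if (axis == "cell_type") return(t(zscore_across_celltypes(t(values))))
  if (ncol(values) < 2L)
    stop_input("z-scoring requires at least 2 cell types, got %d",
               ncol(values))
  mu <- rowMeans(values)
  sd <- apply(values, 1L, stats::sd)
  z <- (values - mu) / sd
  if (any(sd == 0)) {
    warning(sprintf("%d constant row(s) mapped to zero z-scores",
                    sum(sd == 0)))
    z[sd == 0, ] <- 0
  }
  z
}

#' Combined safeguard-repressor score
#'
#' `S = z_expr / max|z_expr| + (-z_motif) / max|z_motif|`, each maximum
#' taken over the whole matrix so that expression specificity and motif
#' bias carry equal weight; an all-zero matrix contributes 0. Every score
#' lies in `[-2, 2]` by construction; high values mark specifically
#' expressed TFs whose binding motifs avoid the host cell type's own
#' signature genes.
#'
#' @param z_expr,z_motif TF x cell-type z-score matrices with identical
#'   dimnames.
#' @param zmax `"abs"` divides by the global maximum absolute value
#'   (default); `"positive"` divides by the global maximum value.
#' @return numeric matrix of scores, TF x cell type.
#' @export
safeguard_scores <- function(z_expr, z_motif, zmax = c("abs", "positive")) {
  zmax <- match.arg(zmax)
  z_expr <- as.matrix(z_expr); z_motif <- as.matrix(z_motif)
  mismatch <- c(setdiff(rownames(z_expr), rownames(z_motif)),
                setdiff(rownames(z_motif), rownames(z_expr)),
                setdiff(colnames(z_expr), colnames(z_motif)),
                setdiff(colnames(z_motif), colnames(z_expr)))
  if (!identical(dim(z_expr), dim(z_motif)) || length(mismatch))
    stop_input("z_expr/z_motif index mismatch%s",
               if (length(mismatch)) paste0(": ",
                 paste(utils::head(unique(mismatch), 5L), collapse = ", "))
               else "")
  z_motif <- z_motif[rownames(z_expr), colnames(z_expr), drop = FALSE]
  norm <- function(z) {
    m <- if (zmax == "abs") max(abs(z)) else max(z)
    if (m == 0) z * 0 else z / m
  }
  norm(z_expr) - norm(z_motif)
}

#' Lifelong expression: aged-atlas criterion
#'
#' TRUE iff (1) the TF's mean expression in the given cell type of the
#' aged atlas is at least half its mean in the same type of the young
#' atlas, and (2) its young mean in that type exceeds its young mean
#' across all cell types (mean of per-type means).
#'
#' @param young,aged normalized [cell_atlas()] objects sharing the cell
#'   type.
#' @param tf gene id of the TF.
#' @param cell_type cell type to test.
#' @param aged_min_ratio threshold on aged/young mean (default 0.5).
#' @return logical.
#' @export
lifelong_aged_filter <- function(young, aged, tf, cell_type,
                                 aged_min_ratio = 0.5) {
  for (a in list(young, aged))
    if (!tf %in% rownames(a$counts)) stop_input("TF absent from atlas: %s", tf)
  ym <- celltype_means(young, tf)[1L, ]
  am <- celltype_means(aged, tf)[1L, ]
  if (!cell_type %in% names(ym) || !cell_type %in% names(am))
    stop_input("cell type absent: %s", cell_type)
  unname(am[cell_type] >= aged_min_ratio * ym[cell_type] &
           ym[cell_type] > mean(ym))
}

#' Lifelong expression: developmental-persistence criterion
#'
#' Within each developmental sample (time point x replicate), a TF is
#' "high" iff its expression lies in the top quartile of all TFs in that
#' sample. Returns TRUE iff the TF is high in strictly more than
#' `min_fraction` of samples.
#'
#' @param dev_table numeric matrix, TF x sample.
#' @param tf TF row id.
#' @param quantile_level quantile defining "high" (default 0.75, the top
#'   quartile).
#' @param min_fraction persistence threshold (default 0.7; strict
#'   inequality).
#' @return logical.
#' @export
lifelong_dev_filter <- function(dev_table, tf, quantile_level = 0.75,
                                min_fraction = 0.7) {
  if (!tf %in% rownames(dev_table))
    stop_input("TF absent from developmental table: %s", tf)
  if (ncol(dev_table) < 1L) stop_input("developmental table has no samples")
  thresholds <- apply(dev_table, 2L, stats::quantile,
                      probs = quantile_level, names = FALSE)
  mean(dev_table[tf, ] >= thresholds) > min_fraction
}

#' Assemble the per-(TF, cell type) safeguard score table
#'
#' @param mean_expr,z_expr,z_motif,scores TF x cell-type matrices.
#' @param lifelong_aged,lifelong_dev optional named logical vectors per TF.
#' @return Long-format data.frame (tf, cell_type, mean_expr, z_expr,
#'   z_motif, score, lifelong_aged, lifelong_dev).
#' @export
safeguard_score_table <- function(mean_expr, z_expr, z_motif, scores,
                                  lifelong_aged = NULL, lifelong_dev = NULL) {
  tfs <- rownames(scores); types <- colnames(scores)
  df <- data.frame(tf = rep(tfs, times = length(types)),
                   cell_type = rep(types, each = length(tfs)),
                   mean_expr = as.vector(mean_expr),
                   z_expr = as.vector(z_expr),
                   z_motif = as.vector(z_motif),
                   score = as.vector(scores),
                   stringsAsFactors = FALSE)
  df$lifelong_aged <- if (is.null(lifelong_aged)) NA else
    unname(lifelong_aged[df$tf])
  df$lifelong_dev <- if (is.null(lifelong_dev)) NA else
    unname(lifelong_dev[df$tf])
  df
}

#' Shortlist safeguard candidates per cell type
#'
#' Within each cell type, TFs are sorted by score descending, ties broken
#' by Z_expression descending and then TF id, and the top `top_k` kept.
#' With `require_lifelong`, only TFs passing both lifelong filters enter
#' the ranking.
#'
#' @param score_table long table from [safeguard_score_table()].
#' @param top_k candidates kept per cell type.
#' @param require_lifelong filter to lifelong TFs before ranking.
#' @return The filtered table with a `rank` column, ordered by cell type
#'   then rank.
#' @export
shortlist <- function(score_table, top_k = 1L, require_lifelong = FALSE) {
  if (top_k < 1L) stop_input("top_k must be >= 1")
  df <- score_table
  if (require_lifelong)
    df <- df[df$lifelong_aged %in% TRUE & df$lifelong_dev %in% TRUE, ,
             drop = FALSE]
  out <- lapply(split(df, df$cell_type), function(d) {
    d <- d[order(-d$score, -d$z_expr, d$tf), , drop = FALSE]
    d <- utils::head(d, top_k)
    d$rank <- seq_len(nrow(d))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
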