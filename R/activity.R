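# Per-cell gene-set module scores, TF activity, the rank-proportion
# transduction filter, and identity-activity correlations.

#' Per-cell gene-set module score with bin-matched controls
#'
#' Genes are binned into `n_bins` equal-frequency bins by mean expression
#' across cells; for each set gene, up to `n_ctrl` control genes are
#' sampled without replacement from its bin (seeded), and the score of a
#' cell is the mean expression of the set genes minus the mean expression
#' of the pooled (unique) control genes. The score is invariant to adding
#' a per-cell constant to all genes and zero on constant-expression data.
#'
#' @param atlas a [cell_atlas()].
#' @param gene_set non-empty character vector of atlas gene ids.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100; capped
#'   at bin size).
#' @param seed integer seed for control sampling.
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(atlas, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (!length(gene_set)) stop_input("gene set is empty")
  missing <- setdiff(gene_set, rownames(atlas$counts))
  if (length(missing))
    stop_input("gene set member(s) absent from atlas: %s",
               paste(utils::head(missing, 5L), collapse = ", "))
  m <- atlas$counts
  means <- rowMeans(m)
  n_bins <- min(n_bins, nrow(m))
  # equal-frequency bins by rank of mean expression
  bin <- ceiling(rank(means, ties.method = "first") * n_bins / nrow(m))
  ctrl <- with_local_seed(seed, {
    picks <- lapply(gene_set, function(g) {
      pool <- rownames(m)[bin == bin[match(g, rownames(m))]]
      sample(pool, min(n_ctrl, length(pool)))
    })
    unique(unlist(picks))
  })
  colMeans(m[gene_set, , drop = FALSE]) - colMeans(m[ctrl, , drop = FALSE])
}

#' Per-cell TF activity from a regulon
#'
#' Activator mode is the module score of the regulon's targets. Repressor
#' mode is minus the module score of the high-confidence repressed subset
#' (a sign flip, so that cells in which the TF is active - targets
#' repressed - receive high activity).
#'
#' @param atlas a [cell_atlas()].
#' @param regulon a [build_regulon()] object, or a character vector of
#'   target genes.
#' @param mode `"activator"` or `"repressor"`.
#' @inheritParams module_score
#' @return Named numeric vector of activities per cell.
#' @export
tf_activity <- function(atlas, regulon, mode = c("activator", "repressor"),
                        n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(regulon, "regulon")) {
    genes <- if (mode == "repressor") regulon$high_confidence
    else regulon$targets$gene
  } else genes <- regulon
  if (!length(genes))
    stop_input("empty %s gene set for activity scoring",
               if (mode == "repressor") "high-confidence repressed" else "target")
  s <- module_score(atlas, genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed)
  if (mode == "repressor") -s else s
}

#' Rank-proportion filter for untransduced cells
#'
#' For each overexpression (OE) cell, `gfp_prop` is the fraction of
#' control cells with strictly lower activity, and `prox1_prop` the
#' fraction of the other OE cells with strictly higher activity (self
#' excluded; ties count toward neither). Under the `as_published` rule a
#' cell is excluded iff `gfp_prop > prox1_prop`; the `flipped` rule
#' excludes iff `gfp_prop < prox1_prop`, which removes the low-activity OE
#' tail instead (see the package vignette for why both orientations are
#' offered). Control cells are always kept.
#'
#' @param activity named numeric vector of per-cell activities.
#' @param condition factor/character per cell, levels containing
#'   `control` and `OE` (in `names(activity)` order if unnamed).
#' @param rule `"as_published"` or `"flipped"`.
#' @return data.frame (cell, condition, activity, gfp_prop, prox1_prop,
#'   kept); proportions are `NA` for control cells.
#' @export
filter_untransduced <- function(activity, condition,
                                rule = c("as_published", "flipped")) {
  rule <- match.arg(rule)
  condition <- as.character(condition)
  is_oe <- condition == "OE"
  n_ctrl <- sum(!is_oe); n_oe <- sum(is_oe)
  if (n_ctrl < 2L || n_oe < 2L)
    stop_input("each condition needs at least 2 cells (control %d, OE %d)",
               n_ctrl, n_oe)
  a_ctrl_sorted <- sort(activity[!is_oe])
  a_oe <- activity[is_oe]
  a_oe_sorted <- sort(a_oe)
  # strictly-lower / strictly-higher counts via sorted-vector search
  gfp <- findInterval(a_oe, a_ctrl_sorted, left.open = TRUE) / n_ctrl
  higher <- n_oe - findInterval(a_oe, a_oe_sorted)   # ties excluded, so is self
  prox1 <- higher / (n_oe - 1L)
  excluded <- if (rule == "as_published") gfp > prox1 else gfp < prox1
  gfp_prop <- prox1_prop <- rep(NA_real_, length(activity))
  gfp_prop[is_oe] <- gfp; prox1_prop[is_oe] <- prox1
  kept <- rep(TRUE, length(activity))
  kept[is_oe] <- !excluded
  data.frame(cell = names(activity) %||% seq_along(activity),
             condition = condition, activity = unname(activity),
             gfp_prop = gfp_prop, prox1_prop = prox1_prop, kept = kept,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of identity scores with TF activity
#'
#' @param identity_scores numeric matrix, cells x gene sets (module scores
#'   per cell-type identity set), or a named list of per-cell vectors.
#' @param activity named numeric vector of per-cell TF activity.
#' @param kept optional logical per cell; correlation restricted to kept
#'   cells.
#' @return Named numeric vector of Pearson r per gene set; `NA` with a
#'   warning where either vector has zero variance.
#' @export
identity_activity_correlation <- function(identity_scores, activity,
                                          kept = NULL) {
  if (is.list(identity_scores))
    identity_scores <- do.call(cbind, identity_scores)
  identity_scores <- as.matrix(identity_scores)
  if (is.null(kept)) kept <- rep(TRUE, length(activity))
  if (sum(kept) < 3L) stop_input("need at least 3 kept cells")
  act <- activity[kept]
  vapply(colnames(identity_scores) %||% seq_len(ncol(identity_scores)),
         function(j) {
           x <- identity_scores[kept, j]
           if (stats::sd(x) == 0 || stats::sd(act) == 0) {
             warning(sprintf("zero variance for gene set %s; r undefined", j))
             return(NA_real_)
           }
           stats::cor(x, act)
         }, numeric(1))
}
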