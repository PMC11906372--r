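# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (quadratic scans, exhaustive enumeration) and never
# share code with the implementation they check.

small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_cell_types = 3L, cells_per_type = 30L, n_genes = 300L,
         n_tfs = 12L, markers_per_type = 30L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# atlas with exact values, bypassing normalization
toy_atlas <- function(mat, labels, normalization = "median_cpm") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  cell_atlas(mat, labels, normalization)
}

# O(hits x windows) interval scan: midpoint-in-window counting
brute_count_hits <- function(hits, windows) {
  tfs <- sort(unique(hits$tf))
  occ <- matrix(0L, length(tfs), nrow(windows),
                dimnames = list(tfs, windows$gene))
  for (i in seq_len(nrow(hits))) {
    mid <- (hits$start[i] + hits$end[i]) / 2
    for (j in seq_len(nrow(windows))) {
      if (hits$chrom[i] == windows$chrom[j] &&
          mid >= windows$start[j] && mid < windows$end[j])
        occ[hits$tf[i], j] <- occ[hits$tf[i], j] + 1L
    }
  }
  occ
}

# O(n^2) transduction filter: literal per-cell proportion counting
brute_filter <- function(activity, condition, rule = "as_published") {
  is_oe <- condition == "OE"
  ctrl <- activity[!is_oe]
  kept <- rep(TRUE, length(activity))
  gfp <- prox1 <- rep(NA_real_, length(activity))
  for (i in which(is_oe)) {
    g <- sum(ctrl < activity[i]) / length(ctrl)
    others <- activity[setdiff(which(is_oe), i)]
    p <- sum(others > activity[i]) / length(others)
    gfp[i] <- g; prox1[i] <- p
    kept[i] <- if (rule == "as_published") !(g > p) else !(g < p)
  }
  list(kept = kept, gfp = gfp, prox1 = prox1)
}

# Exhaustive hypergeometric tail: fraction of n-subsets of 1..N whose
# overlap with 1..K is >= k
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}
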