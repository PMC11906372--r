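# Gene-set enrichment and overlap statistics: one-tailed hypergeometric
# enrichment, Fisher overlap of two sets, Benjamini-Hochberg adjustment,
# and a half-up percentage formatter for count ratios.

#' One-tailed hypergeometric gene-set enrichment
#'
#' For each marker set, tests whether the query over-represents the set
#' within the universe: `p = P(X >= k)` with `X ~ Hypergeom(N, K, n)`,
#' where `N` is the universe size, `K` the (universe-intersected) set
#' size, `n` the query size and `k` the overlap. P-values are BH-adjusted
#' across all sets tested together. Only the enrichment (upper) tail is
#' offered.
#'
#' @param query_genes character vector, must be a subset of `universe`.
#' @param marker_sets named list of character vectors.
#' @param universe character vector of all considered genes.
#' @return data.frame (set, N, K, n, k, p, p_adj).
#' @export
hypergeom_enrichment <- function(query_genes, marker_sets, universe) {
  if (!length(universe)) stop_input("universe is empty")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  stray <- setdiff(query_genes, universe)
  if (length(stray))
    stop_input("query gene(s) outside universe: %s",
               paste(utils::head(stray, 5L), collapse = ", "))
  N <- length(universe); n <- length(query_genes)
  res <- lapply(names(marker_sets), function(s) {
    set <- intersect(unique(marker_sets[[s]]), universe)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    data.frame(set = s, N = N, K = K, n = n, k = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Fisher overlap test of two gene sets
#'
#' Builds the 2x2 membership table of `set_a` x `set_b` over the universe
#' and reports the sample odds ratio (`ad/bc`; infinite when `bc = 0`) and
#' the one-tailed enrichment p-value from the upper hypergeometric tail.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all considered genes.
#' @return list(odds_ratio, p, table) where `table` is the 2x2 matrix
#'   (in/out of a x in/out of b).
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop_input("universe is empty")
  universe <- unique(universe)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_a", "out_a"), c("in_b", "out_b")))
  p <- stats::phyper(a - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(odds_ratio = (a * d) / (b * cc), p = p, table = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' preserved.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Percentage of a count ratio, rounded half-up
#'
#' `100 * k / n` rounded half-up to `decimals` digits - the convention of
#' printed count ratios such as "4,074 of 4,353 (93.6%)".
#'
#' @param k,n non-negative counts with `k <= n`, `n > 0`.
#' @param decimals digits kept (default 1).
#' @return numeric percentage.
#' @export
fraction_percent <- function(k, n, decimals = 1L) {
  if (any(n <= 0)) stop_input("n must be > 0")
  if (any(k < 0 | k > n)) stop_input("k must lie in [0, n]")
  f <- 10^decimals
  floor(100 * k / n * f + 0.5) / f
}
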