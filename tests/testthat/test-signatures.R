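# Normalization, one-vs-rest marker ranking, and signature overlap removal.

test_that("median CPM scales cells to the median library size", {
  m <- matrix(c(40, 60, 120, 80, 150, 150), nrow = 2)
  atlas <- toy_atlas(m, labels = c("A", "A", "B"), normalization = "raw")
  norm <- median_normalize_cpm(atlas)
  # totals 100, 200, 300 -> scale factors 2, 1, 2/3
  expect_equal(unname(colSums(norm$counts)), c(200, 200, 200))
  expect_equal(norm$counts[, 1], atlas$counts[, 1] * 2)
  expect_equal(norm$counts[, 3], atlas$counts[, 3] * 2 / 3)
  expect_equal(norm$normalization, "median_cpm")

  # equal totals: identity
  m2 <- matrix(c(1, 9, 4, 6, 2, 8), nrow = 2)
  eq <- median_normalize_cpm(toy_atlas(m2, c("A", "A", "B"), "raw"))
  expect_equal(eq$counts, toy_atlas(m2, c("A", "A", "B"))$counts)

  # single cell: its own total is the median
  one <- median_normalize_cpm(toy_atlas(matrix(c(3, 7), 2, 1,
                                               dimnames = list(c("g1", "g2"),
                                                               "c1")),
                                        "A", "raw"))
  expect_equal(unname(one$counts[, 1]), c(3, 7))

  # within-cell ratios conserved
  m3 <- matrix(rpois(60, 5) + 1, nrow = 6)
  n3 <- median_normalize_cpm(toy_atlas(m3, rep(c("A", "B"), 5), "raw"))
  expect_equal(unname(n3$counts[1, ] / n3$counts[2, ]), m3[1, ] / m3[2, ])

  # zero-total cell is a data error naming the cell
  mz <- matrix(c(1, 2, 0, 0), nrow = 2,
               dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(median_normalize_cpm(cell_atlas(mz, c("A", "B"))), "empty")
})

test_that("marker ranking orders by evidence and matches the exact test", {
  # exclusive target-type gene must outrank a uniform gene
  m <- rbind(excl = c(10, 10, 10, 0, 0, 0),
             unif = c(5, 5, 5, 5, 5, 5))
  atlas <- toy_atlas(m, rep(c("T", "R"), each = 3))
  top <- rank_markers(atlas, "T", n_top = 2)
  expect_equal(top$gene[1], "excl")

  # {5,6,7} vs {1,2,3}: exact one-sided rank-sum p = 1/C(6,3)
  m2 <- rbind(g1 = c(5, 6, 7, 1, 2, 3))
  p <- rank_markers(toy_atlas(m2, rep(c("T", "R"), each = 3)), "T",
                    n_top = 1)$p_value
  expect_equal(p, 0.05)

  # n_top beyond the gene count returns everything, no padding
  all_g <- rank_markers(atlas, "T", n_top = 50)
  expect_equal(nrow(all_g), 2)

  expect_error(rank_markers(atlas, "missing_type"), "unknown cell type")
  expect_error(rank_markers(atlas, "T", n_top = 0), "n_top")
})

test_that("vectorised rank-sum p-values agree with stats::wilcox.test", {
  set.seed(71)
  # tie-free small samples: exact path
  m <- matrix(runif(10 * 14), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:14)))
  grp <- rep(c(TRUE, FALSE), c(6, 8))
  p <- safeguardR:::rowwise_wilcox_greater(m, grp)
  ref <- apply(m, 1, function(x)
    wilcox.test(x[grp], x[!grp], alternative = "greater")$p.value)
  expect_equal(p, unname(ref))

  # tied counts, large sample: tie-corrected normal approximation
  m2 <- matrix(rpois(20 * 60, 3), nrow = 20,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:60)))
  grp2 <- rep(c(TRUE, FALSE), c(25, 35))
  p2 <- safeguardR:::rowwise_wilcox_greater(m2, grp2)
  ref2 <- apply(m2, 1, function(x)
    suppressWarnings(wilcox.test(x[grp2], x[!grp2],
                                 alternative = "greater")$p.value))
  expect_equal(p2, unname(ref2), tolerance = 1e-10)
})

test_that("overlap removal leaves pairwise-disjoint signatures", {
  sig <- function(genes) data.frame(gene = genes,
                                    log2_fc = seq_along(genes),
                                    p_value = 0.01, p_adj = 0.01,
                                    rank = seq_along(genes))
  sigs <- structure(list(A = sig(c("shared", "a1", "a2")),
                         B = sig(c("b1", "shared", "b2")),
                         C = sig(c("c1", "c2"))),
                    class = "signature_table")
  dd <- deduplicate_signatures(sigs)
  expect_equal(dd$A$gene, c("a1", "a2"))
  expect_equal(dd$B$gene, c("b1", "b2"))
  expect_equal(dd$C$gene, c("c1", "c2"))

  # disjoint input is returned unchanged
  expect_equal(deduplicate_signatures(dd)$A, dd$A)

  # identical signatures collapse to nothing
  same <- structure(list(A = sig(c("x", "y")), B = sig(c("x", "y"))),
                    class = "signature_table")
  empty <- deduplicate_signatures(same)
  expect_equal(vapply(empty, nrow, 1L), c(A = 0L, B = 0L))
})

test_that("planted markers fill their type's deduplicated signature", {
  for (s in 1:5) {
    cfg <- small_cfg(seed = s)
    sim <- simulate_atlas(cfg)
    atlas <- median_normalize_cpm(sim$atlas)
    genes <- sprintf("gene%04d", 1:cfg$n_genes)
    sigs <- deduplicate_signatures(
      build_signatures(atlas, n_top = 50, genes = genes))
    # pairwise disjoint, exhaustively
    types <- names(sigs)
    for (i in seq_along(types))
      for (j in seq_len(i - 1L))
        expect_length(intersect(sigs[[i]]$gene, sigs[[j]]$gene), 0)
    recovered <- vapply(types, function(ct) {
      planted <- sim$truth$marker_assignment$gene[
        sim$truth$marker_assignment$home_type == ct]
      mean(planted %in% sigs[[ct]]$gene)
    }, numeric(1))
    expect_true(all(recovered >= 0.9))
  }
})
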