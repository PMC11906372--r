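# Regulon construction, module/activity scores, transduction filtering
# and identity-activity correlations.

test_that("peaks annotate to genes by half-open TSS proximity", {
  ann <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(10000L, 12100L), strand = "+")
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  expect_equal(annotate_peaks_to_genes(pk(9500L, 9600L), ann)$gene, "g1")
  # window is [9000, 11000): a peak starting at 11000 misses it
  expect_equal(nrow(annotate_peaks_to_genes(pk(11000L, 11100L), ann)), 0)
  # one peak spanning both windows maps to both genes
  both <- annotate_peaks_to_genes(pk(10900L, 11300L), ann)
  expect_setequal(both$gene, c("g1", "g2"))
  expect_error(annotate_peaks_to_genes(pk(10L, 5L), ann), "malformed")
})

test_that("motif support extends hits to fixed width and filters peaks", {
  # 11-base hit [999, 1010) extended to 50 -> [980, 1030)
  hit <- data.frame(chrom = "chr1", start = 999L, end = 1010L)
  grazing <- data.frame(chrom = "chr1", start = 970L, end = 981L)
  outside <- data.frame(chrom = "chr1", start = 970L, end = 980L)
  expect_equal(nrow(intersect_peaks_with_motifs(grazing, hit)), 1)
  expect_equal(nrow(intersect_peaks_with_motifs(outside, hit)), 0)
  tail_end <- data.frame(chrom = "chr1", start = 1029L, end = 1040L)
  past_end <- data.frame(chrom = "chr1", start = 1030L, end = 1040L)
  expect_equal(nrow(intersect_peaks_with_motifs(tail_end, hit)), 1)
  expect_equal(nrow(intersect_peaks_with_motifs(past_end, hit)), 0)

  peaks <- rbind(grazing, outside, tail_end)
  expect_equal(nrow(intersect_peaks_with_motifs(peaks, hit[0, ])), 0)
  # every peak supported -> identity
  covering <- data.frame(chrom = "chr1", start = c(900L, 1000L),
                         end = c(1100L, 1020L))
  expect_equal(intersect_peaks_with_motifs(covering, hit), covering)
})

test_that("regulon targets require peak, motif and expression evidence", {
  map <- data.frame(peak = paste0("p", 1:4),
                    gene = c("down_sig", "up_sig", "down_ns", "down_closed"))
  de <- data.frame(gene = c("down_sig", "up_sig", "down_ns", "down_closed",
                            "no_peak"),
                   log2_fc = c(-2, 1.5, -1, -3, -2),
                   p_adj = c(0.001, 0.001, 0.4, 0.001, 0.001))
  acc <- data.frame(gene = c("down_sig", "down_closed"), log2_fc = c(0.2, 2))
  reg <- build_regulon("tfX", map, de, acc)
  expect_setequal(reg$targets$gene, c("down_sig", "up_sig", "down_closed"))
  expect_equal(reg$targets$direction[reg$targets$gene == "up_sig"],
               "activated")
  expect_equal(reg$high_confidence, "down_closed")

  # reversed contrast flips direction calls
  reg_rev <- build_regulon("tfX", map, de, acc, contrast = "control_vs_oe")
  expect_equal(reg_rev$targets$direction[reg_rev$targets$gene == "up_sig"],
               "repressed")

  # unreachable accessibility threshold empties only the subset
  reg_inf <- build_regulon("tfX", map, de, acc, atac_lfc_threshold = Inf)
  expect_length(reg_inf$high_confidence, 0)
  expect_equal(reg_inf$targets$gene, reg$targets$gene)

  expect_equal(nrow(build_regulon("tfX", map[0, ], de)$targets), 0)
  expect_warning(build_regulon("tfX",
                               data.frame(peak = "p", gene = "unseen"), de),
                 "absent")
})

test_that("module scores use bin-matched controls and known invariances", {
  # degenerate single bin, control pool = all genes
  a1 <- toy_atlas(matrix(1:6, ncol = 1,
                         dimnames = list(paste0("g", 1:6), "c1")), "A")
  s <- module_score(a1, c("g5", "g6"), n_bins = 1, n_ctrl = 10, seed = 1)
  expect_equal(unname(s), 2.0)

  # constant across genes within each cell -> zero for any set
  m <- matrix(rep(c(2, 5, 9), each = 4), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  s0 <- module_score(toy_atlas(m, c("A", "A", "B")), c("g1", "g3"),
                     seed = 3)
  expect_equal(unname(s0), c(0, 0, 0))

  # per-cell additive shift leaves scores unchanged
  set.seed(21)
  m2 <- matrix(rexp(300), nrow = 30,
               dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  at <- toy_atlas(m2, rep("A", 10))
  shift <- sweep(m2, 2, seq_len(10), `+`)
  at_shift <- toy_atlas(shift, rep("A", 10))
  expect_equal(module_score(at, c("g1", "g7"), n_bins = 3, seed = 5),
               module_score(at_shift, c("g1", "g7"), n_bins = 3, seed = 5))

  # identical seeds resample identical controls
  expect_equal(module_score(at, "g2", seed = 9), module_score(at, "g2", seed = 9))
  expect_error(module_score(at, character(0)), "empty")
  expect_error(module_score(at, "nope"), "absent")
})

test_that("repressor activity is the negated module score of the subset", {
  set.seed(31)
  m <- matrix(rexp(500), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
  at <- toy_atlas(m, rep(c("control", "OE"), each = 5))
  genes <- c("g3", "g11", "g40")
  expect_equal(tf_activity(at, genes, "repressor", seed = 2),
               -tf_activity(at, genes, "activator", seed = 2))
  reg <- structure(list(tf = "t", targets = data.frame(gene = genes),
                        high_confidence = character(0)), class = "regulon")
  expect_error(tf_activity(at, reg, "repressor"), "high-confidence")
})

test_that("transduction filter reproduces the hand-worked proportions", {
  act <- c(k1 = 1, k2 = 2, k3 = 3, o1 = 1.5, o2 = 10)
  cond <- c("control", "control", "control", "OE", "OE")
  res <- filter_untransduced(act, cond)
  o1 <- res[res$cell == "o1", ]; o2 <- res[res$cell == "o2", ]
  expect_equal(c(o2$gfp_prop, o2$prox1_prop), c(1, 0))
  expect_false(o2$kept)                      # gfp > prox1 under as_published
  expect_equal(c(o1$gfp_prop, o1$prox1_prop), c(1 / 3, 1))
  expect_true(o1$kept)
  flipped <- filter_untransduced(act, cond, rule = "flipped")
  expect_true(flipped$kept[flipped$cell == "o2"])
  expect_false(flipped$kept[flipped$cell == "o1"])
  expect_true(all(res$kept[res$condition == "control"]))

  # all-equal activities: strict comparisons keep everything
  eq <- filter_untransduced(setNames(rep(1, 6), paste0("c", 1:6)),
                            rep(c("control", "OE"), each = 3))
  expect_true(all(eq$kept))
  expect_equal(eq$gfp_prop[4:6], rep(0, 3))
  expect_equal(eq$prox1_prop[4:6], rep(0, 3))

  expect_error(filter_untransduced(act[1:3], c("control", "control", "OE")),
               "at least 2")
})

test_that("transduction filter matches the quadratic oracle with ties", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 200
    act <- setNames(sample(seq(0, 5, by = 0.5), n, TRUE),
                    paste0("c", seq_len(n)))
    cond <- sample(rep(c("control", "OE"), each = n / 2))
    for (rule in c("as_published", "flipped")) {
      got <- filter_untransduced(act, cond, rule = rule)
      ref <- brute_filter(act, cond, rule = rule)
      expect_identical(got$kept, ref$kept)
      expect_equal(got$gfp_prop, ref$gfp)
      expect_equal(got$prox1_prop, ref$prox1)
    }
  }
})

test_that("identity-activity correlation is plain Pearson on kept cells", {
  ids <- cbind(hep = c(1, 2, 3, 4), fib = c(4, 3, 2, 1))
  rownames(ids) <- paste0("c", 1:4)
  act <- setNames(c(1, 2, 3, 4), rownames(ids))
  r <- identity_activity_correlation(ids, act)
  expect_equal(unname(r), c(1, -1))

  r2 <- identity_activity_correlation(cbind(s = c(1, 2, 3, 4)),
                                      setNames(c(2, 4, 5, 9), paste0("c", 1:4)))
  expect_equal(unname(r2), 0.9647638, tolerance = 1e-6)

  expect_warning(rz <- identity_activity_correlation(cbind(z = rep(1, 4)),
                                                     act),
                 "zero variance")
  expect_true(is.na(rz))
  expect_error(identity_activity_correlation(ids, act,
                                             kept = c(TRUE, TRUE, FALSE,
                                                      FALSE)),
               "3 kept")
})
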