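# Synthetic-data generator: planted structure, determinism, null cases.

test_that("atlas simulation is seed-deterministic and conserves cells", {
  cfg <- small_cfg(seed = 42L)
  a <- simulate_atlas(cfg)
  b <- simulate_atlas(cfg)
  expect_identical(a$atlas$counts, b$atlas$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(ncol(a$atlas$counts), cfg$n_cell_types * cfg$cells_per_type)
  expect_equal(nrow(a$atlas$counts), cfg$n_genes + cfg$n_tfs)
  expect_false(anyNA(a$atlas$labels))
  expect_equal(length(a$atlas$labels), ncol(a$atlas$counts))
  # roles disjoint, one home type per planted TF
  planted <- a$truth$tf_role[a$truth$tf_role$role != "neutral", ]
  expect_false(anyDuplicated(planted$tf) > 0)
  expect_true(all(!is.na(planted$home_type)))
})

test_that("invalid configurations fail naming the violated invariant", {
  expect_error(sim_config(markers_per_type = 200, n_genes = 300,
                          n_cell_types = 3),
               "markers_per_type")
  expect_error(sim_config(n_tfs = 4, n_cell_types = 4,
                          safeguard_per_type = 1, activator_per_type = 1),
               "safeguard_per_type")
  expect_error(sim_config(marker_fold = 0), "marker_fold")
  expect_error(sim_config(cells_per_type = 0), "cells_per_type")
  expect_error(sim_config(transduction_rate = 1.5), "transduction_rate")
})

marker_home_recovery <- function(sim) {
  means <- celltype_means(sim$atlas, sim$truth$marker_assignment$gene)
  top <- colnames(means)[max.col(means, ties.method = "first")]
  mean(top == sim$truth$marker_assignment$home_type)
}

test_that("planted markers dominate their home type; unit fold is null", {
  cfg <- sim_config(seed = 3L)   # default study conditions, fold 8
  sim <- simulate_atlas(cfg)
  means <- celltype_means(sim$atlas, sim$truth$marker_assignment$gene)
  home <- sim$truth$marker_assignment$home_type
  above <- vapply(seq_len(nrow(means)), function(i)
    means[i, home[i]] > max(means[i, colnames(means) != home[i]]),
    logical(1))
  expect_gt(mean(above), 0.95)

  # marker_fold = 1 plants nothing: recovery at chance level
  null_rates <- vapply(1:5, function(s)
    marker_home_recovery(simulate_atlas(small_cfg(seed = s, marker_fold = 1))),
    numeric(1))
  expect_lt(mean(null_rates), 1 / 3 + 0.1)
  expect_gt(mean(null_rates), 1 / 3 - 0.1)
})

test_that("marker recovery increases weakly with the planted fold", {
  grid <- c(1, 3, 8)
  rates <- vapply(grid, function(fold)
    mean(vapply(1:20, function(s)
      marker_home_recovery(simulate_atlas(small_cfg(seed = s,
                                                    marker_fold = fold))),
      numeric(1))), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("motif hits plant safeguard depletion at own-type markers", {
  cfg <- small_cfg(seed = 5L)
  truth <- plant_truth(cfg)
  ann <- make_tss_annotation(c(sprintf("gene%04d", 1:cfg$n_genes),
                               sprintf("tf%02d", 1:cfg$n_tfs)))
  win <- make_promoter_windows(ann)

  own_vs_other <- function(seed, ...) {
    cfg <- small_cfg(seed = seed, ...)
    truth <- plant_truth(cfg)
    hits <- simulate_motif_hits(truth, ann, cfg)
    occ <- count_motif_hits(hits, win)
    sg <- truth$tf_role[truth$tf_role$role == "safeguard", ]
    vapply(seq_len(nrow(sg)), function(i) {
      own <- truth$marker_assignment$gene[
        truth$marker_assignment$home_type == sg$home_type[i]]
      other <- setdiff(truth$marker_assignment$gene, own)
      mean(occ[sg$tf[i], own]) < mean(occ[sg$tf[i], other])
    }, logical(1))
  }
  # default rates (0.2 vs 3.0): depletion in every seed
  expect_true(all(vapply(1:20, function(s) all(own_vs_other(s)),
                         logical(1))))

  # degenerate rate: exactly zero hits in own-type marker promoters
  hits0 <- simulate_motif_hits(truth, ann,
                               small_cfg(seed = 5L, motif_rate_low = 0))
  occ0 <- count_motif_hits(hits0, win)
  sg <- truth$tf_role[truth$tf_role$role == "safeguard", ][1, ]
  own <- truth$marker_assignment$gene[
    truth$marker_assignment$home_type == sg$home_type]
  expect_true(all(occ0[sg$tf, own] == 0))

  # equal rates: no planted depletion signal
  eq <- own_vs_other(5L, motif_rate_low = 1.5, motif_rate_high = 1.5)
  expect_lt(mean(eq), 1)  # direction at chance, not forced

  # marker gene absent from annotation is a data error
  drop <- ann[ann$gene != truth$marker_assignment$gene[1], ]
  expect_error(simulate_motif_hits(truth, drop, cfg), "annotation")
})

test_that("aged and developmental series honor the lifelong thresholds", {
  cfg <- small_cfg(seed = 9L)
  sim <- simulate_atlas(cfg)
  safeguards <- sim$truth$tf_role$tf[sim$truth$tf_role$role == "safeguard"]
  homes <- sim$truth$tf_role$home_type[sim$truth$tf_role$role == "safeguard"]

  young <- median_normalize_cpm(sim$atlas)

  # full retention: every planted safeguard passes both criteria
  ser <- simulate_aging_and_dev_series(sim$truth, cfg, aged_fraction = 1.0)
  aged <- median_normalize_cpm(ser$aged)
  for (i in seq_along(safeguards))
    expect_true(lifelong_aged_filter(young, aged, safeguards[i], homes[i]))

  # one TF dropped to 40% of young expression fails the 50% criterion
  drop <- setNames(0.4, safeguards[1])
  ser2 <- simulate_aging_and_dev_series(sim$truth, cfg, aged_fraction = drop)
  aged2 <- median_normalize_cpm(ser2$aged)
  expect_false(lifelong_aged_filter(young, aged2, safeguards[1], homes[1]))

  # persistence 0.8 over 10 time points -> lifelong; 0.7 is not > 70%
  ser3 <- simulate_aging_and_dev_series(sim$truth, cfg, persistence = 0.8,
                                        n_timepoints = 10, n_replicates = 1)
  expect_true(lifelong_dev_filter(ser3$dev, safeguards[1]))
  ser4 <- simulate_aging_and_dev_series(sim$truth, cfg, persistence = 0.7,
                                        n_timepoints = 10, n_replicates = 1)
  expect_false(lifelong_dev_filter(ser4$dev, safeguards[1]))
})

test_that("reprogramming plants latent transduction with target repression", {
  cfg <- small_cfg(seed = 2L)
  truth <- plant_truth(cfg)

  rep0 <- simulate_reprogramming(truth, small_cfg(seed = 2L,
                                                  transduction_rate = 0))
  expect_false(any(rep0$truth$transduced))

  # repression_factor 1: regulon-target means coincide across conditions
  rep1 <- simulate_reprogramming(truth, small_cfg(seed = 2L,
                                                  repression_factor = 1))
  m <- rep1$atlas$counts[rep1$truth$regulon, ]
  oe <- rep1$atlas$labels == "OE"
  expect_lt(abs(mean(m[, oe]) - mean(m[, !oe])), 0.15)

  # default rate 0.7 / factor 0.2: transduced cells repress targets
  for (s in 1:5) {
    rp <- simulate_reprogramming(plant_truth(small_cfg(seed = s)),
                                 small_cfg(seed = s))
    tg <- rp$atlas$counts[rp$truth$regulon, ]
    oe <- rp$atlas$labels == "OE"
    tr <- rp$truth$transduced
    expect_lt(mean(tg[, oe & tr]), mean(tg[, oe & !tr]))
  }
})
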