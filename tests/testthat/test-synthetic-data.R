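test_that("simulate_genome is deterministic and validates proportions", {
  g1 <- simulate_genome(n_chroms = 1, chrom_length = 1e7, n_genes = 100,
                        n_enhancers = 500, seed = 7)
  g2 <- simulate_genome(n_chroms = 1, chrom_length = 1e7, n_genes = 100,
                        n_enhancers = 500, seed = 7)
  expect_identical(g1, g2)
  g3 <- simulate_genome(n_chroms = 1, chrom_length = 1e7, n_genes = 100,
                        n_enhancers = 500, seed = 8)
  expect_false(identical(g1$truth$base_mean, g3$truth$base_mean))
  expect_error(simulate_genome(class_proportions = c(0.5, 0.3, 0.3, 0.0)),
               "summing to 1")
  all_unchanged <- simulate_genome(n_enhancers = 100, n_genes = 20,
                                   chrom_length = 5e6,
                                   class_proportions = c(1, 0, 0, 0), seed = 2)
  expect_true(all(all_unchanged$truth$class == "UNCHANGED"))
  expect_error(simulate_genome(n_genes = 1e5, n_enhancers = 1e5,
                               chrom_length = 1e6), "placement error")
})

test_that("simulated layout respects gene gaps and the regular-enhancer filter", {
  g <- simulate_genome(n_chroms = 2, chrom_length = 1e7, n_genes = 120,
                       n_enhancers = 400, seed = 3)
  # genes non-overlapping
  gs <- g$genes[order(g$genes$chrom, g$genes$start), ]
  same <- gs$chrom[-1] == gs$chrom[-nrow(gs)]
  expect_true(all(gs$start[-1][same] >= gs$end[-nrow(gs)][same]))
  # every enhancer passes the >5 kb regular-enhancer filter
  kept <- filter_regular_enhancers(as.data.frame(g$truth), g$genes)
  expect_equal(nrow(kept), nrow(g$truth))
  # distractors land inside gene bodies and are filtered out
  gd <- simulate_genome(n_chroms = 1, chrom_length = 1e7, n_genes = 60,
                        n_enhancers = 200, n_distractors = 30, seed = 4)
  tr <- as.data.frame(gd$truth)
  expect_equal(sum(tr$distractor), 30)
  kept2 <- filter_regular_enhancers(tr, gd$genes)
  expect_true(all(!kept2$distractor))
  expect_equal(nrow(kept2), 200)
})

test_that("planted lfcs satisfy the class constraints", {
  g <- simulate_genome(n_chroms = 1, chrom_length = 2e7, n_genes = 50,
                       n_enhancers = 1000, seed = 11,
                       class_proportions = c(0.4, 0.25, 0.2, 0.15))
  tr <- g$truth
  expect_true(all(tr$lfc_k27[tr$class == "UNCHANGED"] == 0))
  expect_true(all(tr$lfc_k27[grepl("^GAINED", tr$class)] > 0))
  expect_true(all(tr$lfc_brd4[tr$class == "GAINED_BRD4_INDEPENDENT"] <= 0))
  expect_true(all(tr$lfc_brd4[tr$class == "GAINED_BRD4_INDEPENDENT"] >= -1.5))
  expect_true(all(tr$lfc_brd4[tr$class == "GAINED_BRD4_DEPENDENT"] > 0))
  expect_true(all(tr$lfc_k27[tr$class == "LOST"] < 0))
  expect_true(all(tr$base_mean > 0))
})

test_that("chip experiments are deterministic and hit exact means in the noiseless limit", {
  g <- simulate_genome(n_chroms = 1, chrom_length = 5e6, n_genes = 20,
                       n_enhancers = 100, seed = 5, dispersion = 0)
  e1 <- simulate_chip_experiment(g$truth, "resistant", "h3k27ac")
  e2 <- simulate_chip_experiment(g$truth, "resistant", "h3k27ac")
  expect_identical(e1$track, e2$track)
  expect_identical(e1$peaks, e2$peaks)
  # dispersion 0, background off: resistant/parental track ratio is 2^lfc exactly
  ep <- simulate_chip_experiment(g$truth, "parental", "h3k27ac", background_rate = 0)
  er <- simulate_chip_experiment(g$truth, "resistant", "h3k27ac", background_rate = 0)
  gained <- which(g$truth$lfc_k27 == 2)
  expect_true(length(gained) > 0)
  expect_equal(er$counts[gained] / ep$counts[gained], rep(4, length(gained)))
  expect_error(simulate_chip_experiment(g$truth, "parental", "h3k27ac",
                                        depth_scale = 0), "> 0")
})

test_that("per-class mean log2 count ratios recover the planted lfcs (mean law)", {
  g <- simulate_genome(n_chroms = 1, chrom_length = 4e7, n_genes = 50,
                       n_enhancers = 2000, seed = 21, dispersion = 0.05,
                       class_proportions = c(0.25, 0.25, 0.25, 0.25))
  lfcs <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    ep <- simulate_chip_experiment(g$truth, "parental", "h3k27ac",
                                   seed = 1000 + r, background_rate = 0)
    er <- simulate_chip_experiment(g$truth, "resistant", "h3k27ac",
                                   seed = 2000 + r, background_rate = 0)
    ratio <- log2((er$counts + 1) / (ep$counts + 1))
    lfcs[r, 1] <- mean(ratio[grepl("^GAINED", g$truth$class)])
    lfcs[r, 2] <- mean(ratio[g$truth$class == "LOST"])
  }
  expect_lt(abs(mean(lfcs[, 1]) - 2), 0.15)
  expect_lt(abs(mean(lfcs[, 2]) + 2), 0.15)
})

test_that("base means are heavy-tailed (top decile carries a large signal share)", {
  g <- simulate_genome(n_chroms = 1, chrom_length = 4e7, n_genes = 50,
                       n_enhancers = 2000, seed = 9, tail_shape = 1.5)
  bm <- sort(g$truth$base_mean, decreasing = TRUE)
  top_decile_share <- sum(bm[1:200]) / sum(bm)
  expect_gt(top_decile_share, 0.4)
  expect_equal(mean(g$truth$base_mean > 0), 1)
})

test_that("simulated dose matrices obey the Bliss null and planted interaction", {
  # interaction 0, noise 0: excess identically 0 to machine precision
  b0 <- bliss_excess(simulate_dose_matrix(combo_truth(1, 0.05)))
  expect_identical(max(abs(b0$excess)), 0)
  # planted +0.2, no noise: every unclipped combination cell at exactly +0.2
  b <- bliss_excess(simulate_dose_matrix(combo_truth(1, 0.05, interaction = 0.2)))
  unclipped <- b$expected + 0.2 <= 1
  unclipped[1, ] <- FALSE; unclipped[, 1] <- FALSE
  expect_true(any(unclipped))
  expect_equal(max(abs(b$excess[unclipped] - 0.2)), 0, tolerance = 1e-12)
  # hill 1, ic50 1, dose 1 -> FA 0.5 on the single-agent margin
  dm <- simulate_dose_matrix(combo_truth(1, 1))
  expect_equal(dm$fa[which(dm$doses_a == 1), 1], 0.5)
  # dose grids ascend from 0 and bracket the IC50
  expect_equal(dm$doses_a[1], 0)
  expect_true(all(diff(dm$doses_a) > 0))
  expect_true(min(dm$doses_a[-1]) < 1 && max(dm$doses_a) > 1)
  # determinism under noise
  n1 <- simulate_dose_matrix(combo_truth(1, 1, noise_sd = 0.05, seed = 3))
  n2 <- simulate_dose_matrix(combo_truth(1, 1, noise_sd = 0.05, seed = 3))
  expect_identical(n1, n2)
  expect_error(combo_truth(1, 1, noise_sd = -0.1), ">= 0")
  expect_error(combo_truth(-1, 1), "> 0")
})
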