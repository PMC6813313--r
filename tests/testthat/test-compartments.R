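# compartment-only checkerboard study, reused across blocks in this file
comp_truth <- simulate_truth(
  sim_config(n_tads = 0L, n_diff_boundaries = 0L, n_gain_tads = 0L,
             n_chromatin_tads = 0L, n_flips = 1L), seed = 1)

test_that("PC1 recovers planted labels and is scale invariant", {
  cm <- simulate_contact_map(comp_truth, "low", 5e6, 21, bin_size = 5e4)
  b <- ice_normalize(cm)
  pc1 <- compute_pc1(b, comp_truth$peaks$h3k27ac)
  mids <- (pc1$start + pc1$end) / 2
  lab <- tadlink:::comp_label_at(comp_truth, mids, "low")
  ok <- pc1$label %in% c("A", "B")
  expect_gt(mean(pc1$label[ok] == lab[ok]), 0.98)

  b2 <- b; b2$counts <- b$counts * 2
  pc1b <- compute_pc1(b2, comp_truth$peaks$h3k27ac)
  expect_identical(pc1$label, pc1b$label)

  # orientation follows the active peaks: peaks placed only in planted B
  # bins force those bins positive
  bcomp <- comp_truth$compartments[comp_truth$compartments$label_low == "B", ]
  fake_active <- data.frame(chrom = bcomp$chrom,
                            start = (bcomp$start + bcomp$end) / 2 - 500,
                            end = (bcomp$start + bcomp$end) / 2 + 500)
  pc1c <- compute_pc1(b, fake_active)
  in_b <- lab == "B" & pc1c$label %in% c("A", "B")
  expect_gt(mean(pc1c$pc1[in_b] > 0, na.rm = TRUE), 0.9)
})

test_that("PC1 is reproducible across Poisson replicates", {
  b1 <- ice_normalize(simulate_contact_map(comp_truth, "low", 5e6, 61,
                                           bin_size = 5e4))
  b2 <- ice_normalize(simulate_contact_map(comp_truth, "low", 5e6, 62,
                                           bin_size = 5e4))
  p1 <- compute_pc1(b1, comp_truth$peaks$h3k27ac)
  p2 <- compute_pc1(b2, comp_truth$peaks$h3k27ac)
  expect_gt(cor(p1$pc1, p2$pc1, use = "complete.obs"), 0.9)
})

test_that("saddle matrix and strengths have their closed forms on constructed input", {
  # uniform O/E: saddle identically 0 (log2 of 1), strengths exactly 1
  n <- 120
  cm <- toy_cm(matrix(4, n, n), bin_size = 5e4)
  pc1 <- data.frame(chrom = "cT", start = cm$bins$start, end = cm$bins$end,
                    pc1 = seq(-1, 1, length.out = n),
                    label = rep(c("B", "A"), each = n / 2))
  sad <- saddle_matrix(pc1, cm, n_groups = 10)
  expect_true(all(abs(sad$saddle) < 1e-12))
  st <- compartment_strength(sad)
  expect_equal(st$strength_schwarzer, 1)
  expect_equal(st$strength_nora, 1)

  # constructed corners AA = BB = 2, AB = 0.5: Schwarzer strength 4
  fake <- structure(list(AA = 2, BB = 2, AB = 0.5, BA = 0.5,
                         corner_values = list(same = c(2, 2, 2),
                                              cross = c(0.5, 0.5, 0.5))),
                    class = "saddle_result")
  stf <- compartment_strength(fake)
  expect_equal(stf$strength_schwarzer, 4)
  expect_equal(stf$strength_nora, 4)

  # relabeling A and B leaves both metrics unchanged (formula symmetry)
  swapped <- fake
  swapped$AA <- fake$BB; swapped$BB <- fake$AA
  sts <- compartment_strength(swapped)
  expect_equal(sts, stf)

  # rank partition: groups differ in size by at most one
  n2 <- 503
  cm2 <- toy_cm(matrix(1, n2, n2), bin_size = 5e4)
  pc2 <- data.frame(chrom = "cT", start = cm2$bins$start,
                    end = cm2$bins$end,
                    pc1 = rnorm(n2), label = "A")
  sad2 <- saddle_matrix(pc2, cm2, n_groups = 50)
  expect_lte(diff(range(sad2$group_sizes)), 1L)
  expect_error(saddle_matrix(pc2[1:40, ], toy_cm(matrix(1, 40, 40), 5e4),
                             n_groups = 50), "fewer")
})

test_that("switching detection requires both a sign flip and a profile change", {
  # identical conditions: everything stable
  b <- ice_normalize(simulate_contact_map(comp_truth, "low", 2e6, 71,
                                          bin_size = 5e4))
  pc1 <- compute_pc1(b, comp_truth$peaks$h3k27ac)
  sw_same <- detect_switching(pc1, pc1, b, b)
  expect_true(all(sw_same$class == "Stable"))

  # a sign flip with high profile correlation stays stable
  flipped <- pc1
  flipped$pc1 <- -pc1$pc1
  flipped$label <- ifelse(pc1$label == "A", "B",
                          ifelse(pc1$label == "B", "A", pc1$label))
  sw_flip <- detect_switching(flipped, pc1, b, b, corr_threshold = 0.4)
  expect_true(all(sw_flip$class == "Stable"))
})

test_that("weakening the compartment contrast lowers both strength metrics", {
  strengths <- sapply(c(0.2, 0.4), function(g) {
    cfg <- sim_config(n_tads = 0L, n_diff_boundaries = 0L, n_gain_tads = 0L,
                      n_chromatin_tads = 0L, n_flips = 0L, gamma = g)
    tr <- simulate_truth(cfg, seed = 1)
    b <- ice_normalize(simulate_contact_map(tr, "low", 2e6, 81,
                                            bin_size = 5e4))
    p <- compute_pc1(b, tr$peaks$h3k27ac)
    st <- compartment_strength(saddle_matrix(p, b))
    c(st$strength_schwarzer, st$strength_nora)
  })
  expect_true(all(strengths[, 2] > strengths[, 1]))
})
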