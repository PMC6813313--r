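test_that("ground truth is deterministic and placement arithmetic holds", {
  cfg <- sim_config()
  t1 <- simulate_truth(cfg, seed = 1)
  t2 <- simulate_truth(cfg, seed = 1)
  expect_identical(t1$tads, t2$tads)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$peaks$ctcf, t2$peaks$ctcf)

  # 25 TADs on 20 Mb at 40 kb: mean length 800 kb, all above the minimum
  w <- t1$tads$end - t1$tads$start
  expect_equal(mean(w), 8e5)
  expect_true(all(w >= 10 * 4e4))

  # matrices are reproducible under the same replicate seed
  m1 <- simulate_contact_map(t1, "high", 1e5, 7)
  m2 <- simulate_contact_map(t1, "high", 1e5, 7)
  expect_identical(m1$counts, m2$counts)
  expect_error(simulate_contact_map(t1, "high", 0, 7), "positive")

  # tiny depth still yields a valid sparse Poisson matrix
  md <- simulate_contact_map(t1, "high", 1, 7)
  expect_true(all(md$counts >= 0))
  expect_lt(matrix_total(md), 10)
  expect_equal(md$counts, t(md$counts))
  expect_true(all(md$counts == round(md$counts)))
})

test_that("a configuration without planted effects is null everywhere", {
  cfg <- sim_config(n_diff_boundaries = 0L, n_gain_tads = 0L,
                    n_loss_tads = 0L, n_flips = 0L, n_chromatin_tads = 0L,
                    n_diff_ctcf = 0L, n_diff_k27ac = 0L,
                    glm_beta = c(-50, 0, 0, 0, 0))
  tr <- simulate_truth(cfg, seed = 3)
  expect_true(all(tr$peaks$ctcf$true_log2fc == 0))
  expect_true(all(tr$peaks$h3k27ac$true_log2fc == 0))
  expect_true(all(!tr$genes$de_true))
  ft <- simulate_feature_tables(tr, seed = 4)
  expect_true(all(!ft$genes$de_flag))
})

test_that("reported peak statistics reflect the replicate model", {
  # zero replicate noise: reported log2fc equals the planted value exactly
  tr <- simulate_truth(sim_config(), seed = 5)
  ft0 <- simulate_feature_tables(tr, seed = 6, chip_cv = 0)
  expect_equal(ft0$peaks$ctcf$log2fc, tr$peaks$ctcf$true_log2fc)

  # planted log2fc = 2 at CV 0.1 and 3 reps: median reported near 2
  tr2 <- simulate_truth(sim_config(n_k27ac = 300L, n_diff_k27ac = 120L,
                                   n_chromatin_tads = 12L), seed = 7)
  ft <- simulate_feature_tables(tr2, seed = 8)
  diff <- abs(tr2$peaks$h3k27ac$true_log2fc) == 2
  expect_gte(sum(diff), 100)
  med <- median(abs(ft$peaks$h3k27ac$log2fc[diff]))
  expect_gt(med, 1.8)
  expect_lt(med, 2.2)
  # gene invariant: de_flag consistent with reported thresholds
  g <- ft$genes
  expect_identical(g$de_flag, abs(g$log2fc) > 1 & g$qvalue < 0.01)
})

test_that("baseline DE fraction matches the logistic intercept", {
  cfg <- sim_config(n_genes = 10000L, glm_beta = c(-2, 0, 0, 0, 0))
  tr <- simulate_truth(cfg, seed = 9)
  expect_equal(mean(tr$genes$de_true), plogis(-2), tolerance = 0.1)
  expect_lt(abs(mean(tr$genes$de_true) - 0.119), 0.012)
})

test_that("distance decay of a structureless map has exponent near -1", {
  cfg <- sim_config(n_tads = 0L, gamma = 0, n_flips = 0L,
                    n_chromatin_tads = 0L)
  tr <- simulate_truth(cfg, seed = 1)
  cm <- simulate_contact_map(tr, "low", 5e6, 7)
  b <- ice_normalize(cm)
  dp <- decay_profile(b)[[1]]
  s <- 1:200
  fit <- lm(log(dp[s + 1]) ~ log(s + 1))
  expect_lt(abs(coef(fit)[2] + 1), 0.1)
})

test_that("planted intra-TAD enrichment is recovered in observed/expected", {
  cfg <- sim_config(boundary_attenuation = 1, gamma = 0, n_flips = 0L,
                    n_diff_boundaries = 0L, n_gain_tads = 0L,
                    n_chromatin_tads = 0L)
  tr <- simulate_truth(cfg, seed = 1)
  cm <- simulate_contact_map(tr, "low", 5e6, 7)
  b <- ice_normalize(cm)
  oe <- observed_over_expected(b)[[1]]$oe
  mids <- (b$bins$start + b$bins$end) / 2
  tad_of <- rep(NA_integer_, length(mids))
  for (t in seq_len(nrow(tr$tads)))
    tad_of[mids >= tr$tads$start[t] & mids < tr$tads$end[t]] <- t
  same <- outer(tad_of, tad_of, "==")
  d <- abs(outer(seq_along(mids), seq_along(mids), "-"))
  sel <- upper.tri(same) & d <= 10 & d >= 1
  r_intra <- mean(oe[sel & same], na.rm = TRUE)
  r_cross <- mean(oe[sel & !same], na.rm = TRUE)
  expect_gt(r_intra / r_cross, 1.8)
  expect_lt(r_intra / r_cross, 2.2)
})

test_that("simulated matrices are symmetric nonnegative integers with positive marginals", {
  tr <- simulate_truth(sim_config(), seed = 2)
  for (s in c(31, 32)) {
    cm <- simulate_contact_map(tr, "low", 2e6, s)
    expect_equal(cm$counts, t(cm$counts))
    expect_true(all(cm$counts >= 0))
    expect_true(all(cm$counts == round(cm$counts)))
    cov <- rowSums(cm$counts)
    expect_gt(mean(cov > 0), 0.98)
  }
})
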