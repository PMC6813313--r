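test_that("ratio insulation is constant on a uniform matrix and window defaults follow the bin size", {
  n <- 30
  cm <- toy_cm(matrix(5, n, n), bin_size = 1000)
  tr <- ratio_insulation(cm, window_bins = 5)
  interior <- tr[6:(n - 5)]
  expect_true(all(abs(interior - interior[1]) < 1e-12))
  # 40 kb bins with a 500 kb window give 12 bins
  cm40 <- toy_cm(matrix(1, 26, 26), bin_size = 40000)
  tr40 <- ratio_insulation(cm40)
  expect_equal(attr(tr40, "window_bins"), 12L)
})

test_that("a contact-depleted junction scores higher than TAD interiors", {
  n <- 20
  M <- matrix(1, n, n)
  M[1:10, 1:10] <- 10
  M[11:20, 11:20] <- 10
  M[1:10, 11:20] <- 0
  M[11:20, 1:10] <- 0
  cm <- toy_cm(M)
  tr <- ratio_insulation(cm, window_bins = 4)
  # boundary bin (10 or 11) dominates interior bins
  expect_gt(max(tr[10:11]), max(tr[c(6, 15)]))
})

test_that("insulation scores are invariant under global matrix scaling", {
  set.seed(21)
  M <- matrix(rpois(2500, 50), 50)
  M <- M + t(M)  # total ~ 2.5e5
  cm <- toy_cm(M)
  t1 <- ratio_insulation(cm, window_bins = 5)
  cm10 <- cm; cm10$counts <- cm$counts * 10
  t2 <- ratio_insulation(cm10, window_bins = 5)
  ok <- !is.na(t1)
  expect_lt(max(abs(t1[ok] - t2[ok]) / t1[ok]), 1e-3)
})

test_that("flat tracks give one TAD and zero boundaries; degenerate windows warn", {
  n <- 30
  cm <- toy_cm(matrix(5, n, n), bin_size = 1000)
  tr <- ratio_insulation(cm, window_bins = 5)
  calls <- call_tads_and_boundaries(tr, cm$bins)
  expect_equal(nrow(calls$boundaries), 0L)
  expect_equal(nrow(calls$tads), 1L)
  expect_equal(calls$tads$end - calls$tads$start, n * 1000)
  small <- toy_cm(matrix(1, 5, 5), bin_size = 1000)
  expect_warning(ratio_insulation(small, window_bins = 10), "window")
})

test_that("boundary size arithmetic and MBS definitions hold", {
  expect_equal(boundary_size(7, 40000), 280000)
  expect_equal(boundary_size(1, 40000), 40000)
  expect_equal(boundary_size(3, 50000), 150000)

  bins <- make_bins(c(cT = 10000), 1000)
  track <- c(rep(NA, 3), 1, 2, 3, rep(NA, 4))
  bnd <- data.frame(chrom = "cT", start = 3000, end = 6000)
  expect_equal(mean_boundary_score(track, bins, bnd), 2)
  single <- data.frame(chrom = "cT", start = 4000, end = 5000)
  expect_equal(mean_boundary_score(track, bins, single), 2)
  off <- data.frame(chrom = "cT", start = 8000, end = 10000)
  expect_true(is.na(mean_boundary_score(track, bins, off)))
})

test_that("differential boundary testing matches the textbook two-sample formula", {
  bins <- make_bins(c(cT = 6000), 1000)
  bnd <- data.frame(chrom = "cT", start = 0, end = 6000)
  hi <- list(c(2.0, 2.2, 2.1, 2.4, 2.3, 2.2))
  lo <- list(c(1.0, 1.2, 1.1, 0.9, 1.3, 1.1))
  db <- differential_boundaries(hi, lo, bnd, bins)
  # hand-worked pooled-variance t statistic
  a <- hi[[1]]; b <- lo[[1]]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
  expect_equal(db$pvalue, p_hand, tolerance = 1e-12)
  expect_equal(db$mbs_log2fc, log2(mean(a) / mean(b)))

  # identical conditions: zero log2fc, nothing significant
  db0 <- differential_boundaries(lo, lo, bnd, bins)
  expect_equal(db0$mbs_log2fc, 0)
  expect_false(any(db0$significant))

  # MBS log2 fold change of 2,2 vs 1,1 is exactly 1
  hi2 <- list(c(2, 2)); lo2 <- list(c(1, 1))
  bnd2 <- data.frame(chrom = "cT", start = 0, end = 2000)
  expect_warning(db2 <- differential_boundaries(hi2, lo2, bnd2, bins),
                 "zero-variance")
  expect_equal(db2$mbs_log2fc, 1)
  expect_equal(db2$pvalue, 1)
})

test_that("BH adjustment equals the brute-force definition", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    n <- length(p)
    o <- order(p)
    brute <- numeric(n)
    brute[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    brute <- pmin(brute, 1)
    expect_equal(p.adjust(p, "BH"), brute)
  }
})

test_that("peak occupancy uses the one-bin extension rule", {
  bnd <- data.frame(chrom = "cT", start = 80000, end = 120000)
  peaks <- data.frame(
    chrom = "cT",
    start = c(90000, 41000, 159999, 160001),
    end = c(91000, 42000, 160999, 161001),
    feature_id = c("inside", "in_extension", "edge_overlap", "beyond"),
    high_1 = c(10, 10, 10, 10), high_2 = c(12, 12, 12, 12),
    low_1 = c(5, 5, 5, 5), low_2 = c(6, 6, 6, 6))
  occ <- boundary_occupancy(peaks, bnd, bin_size = 40000, extension_bins = 1)
  # extended region is [40000, 160000): three peaks overlap, one is beyond
  expect_equal(occ$n_peaks, 3L)
  expect_equal(occ$occ_high, mean(c(sum(rep(10, 3)), sum(rep(12, 3)))))
  expect_equal(occ$occ_log2fc, log2(33 / 16.5))
  # a boundary with no assigned peaks stays missing
  far <- data.frame(chrom = "cT", start = 5e6, end = 5.04e6)
  occ2 <- boundary_occupancy(peaks, rbind(bnd, far), bin_size = 40000)
  expect_true(is.na(occ2$occ_log2fc[2]))
})

test_that("strengthening a planted boundary increases its expected MBS", {
  mbs <- sapply(c(1, 2, 4), function(fc) {
    cfg <- sim_config(n_diff_boundaries = 23L, boundary_strength_fc = fc,
                      n_gain_tads = 0L, n_flips = 0L, n_chromatin_tads = 0L)
    tr <- simulate_truth(cfg, seed = 2)
    cm <- simulate_contact_map(tr, "high", 3e6, 51)
    b <- ice_normalize(cm)
    trk <- ratio_insulation(b)
    mean(sapply(seq_len(nrow(tr$boundaries)), function(i)
      mean_boundary_score(trk, b$bins, tr$boundaries[i, ])), na.rm = TRUE)
  })
  expect_true(all(diff(mbs) > 0))
})
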