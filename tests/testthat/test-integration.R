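test_that("feature-to-domain assignment follows containment and loop-span rules", {
  tads <- data.frame(chrom = "c1", start = 0, end = 400000)
  pk_in <- data.frame(chrom = "c1", start = 10000, end = 11000)
  pk_edge <- data.frame(chrom = "c1", start = 399500, end = 400500)
  expect_equal(nrow(assign_features_to_domains(pk_in, tads, "common_tad")), 1L)
  expect_equal(nrow(assign_features_to_domains(pk_edge, tads, "common_tad")),
               0L)

  loops <- data.frame(chrom = "c1", start1 = 100000, end1 = 110000,
                      start2 = 300000, end2 = 310000)
  # peak anywhere in the full loop span (anchor1 start to anchor2 end)
  pk_mid <- data.frame(chrom = "c1", start = 200000, end = 200400)
  expect_equal(nrow(assign_features_to_domains(pk_mid, loops, "loop")), 1L)
  # gene body inside the span but promoter window outside: not assigned
  g <- data.frame(chrom = "c1", start = 150000, end = 200000, tss = 150000,
                  strand = "-")
  # '-' strand: promoter [tss, tss+5000) = [150000,155000) is inside here,
  # so use a gene whose promoter lies beyond the span instead
  g2 <- data.frame(chrom = "c1", start = 305000, end = 312000, tss = 312000,
                   strand = "+")
  # promoter [307000, 312000) overlaps span end 310000 -> assigned
  expect_equal(nrow(assign_features_to_domains(
    g2, loops, "loop", feature_is_gene = TRUE)), 1L)
  g3 <- data.frame(chrom = "c1", start = 316000, end = 330000, tss = 316000,
                   strand = "+")
  # promoter [311000, 316000) misses the span [100000, 310000)
  expect_equal(nrow(assign_features_to_domains(
    g3, loops, "loop", feature_is_gene = TRUE)), 0L)
})

test_that("per-domain mean fold changes respect the mode filters", {
  dom <- data.frame(chrom = "c1", start = 0, end = 1e5)
  pk <- data.frame(chrom = "c1", start = c(1e4, 2e4, 3e4),
                   end = c(1.1e4, 2.1e4, 3.1e4),
                   log2fc = c(2, -1, 1.5), qvalue = c(0.2, 0.3, 0.01))
  asg <- assign_features_to_domains(pk, dom, "common_tad")
  expect_equal(domain_mean_lfc(asg, pk, 1, "all"), mean(c(2, -1, 1.5)))
  expect_equal(domain_mean_lfc(asg[1, , drop = FALSE], pk, 1, "all"), 2)
  expect_equal(domain_mean_lfc(asg, pk, 1, "differential", diff_q = 0.05),
               1.5)
  # a domain with no qualifying features is missing
  expect_true(is.na(domain_mean_lfc(asg[0, ], pk, 1, "all")))
})

test_that("binned mark normalization uses median-of-ratios size factors", {
  # equal counts in both conditions: zero fold change
  ch <- matrix(c(100, 100, 50, 50, 80, 80), 3, 2, byrow = TRUE)
  cl <- ch
  expect_equal(binned_mark_lfc(ch, cl), rep(0, 3))

  # doubled counts with size factors forced equal: log2 ratio near 1
  big <- matrix(rep(c(2e4, 1e4, 3e4), 2), 3, 2)
  lfc <- binned_mark_lfc(2 * big, big, size_factors = rep(1, 4))
  expect_equal(lfc, rep(1, 3), tolerance = 1e-3)

  # hand-worked median-of-ratios oracle on a 3-region, 2+2-replicate table
  cnts <- matrix(c(100, 120, 50, 60,
                   200, 210, 100, 120,
                   400, 380, 220, 200), 3, 4, byrow = TRUE)
  ref <- exp(rowMeans(log(cnts)))
  sf_hand <- apply(cnts / ref, 2, median)
  lfc_pkg <- binned_mark_lfc(cnts[, 1:2], cnts[, 3:4])
  norm <- sweep(cnts, 2, sf_hand, "/")
  lfc_hand <- log2((rowMeans(norm[, 1:2]) + 1) / (rowMeans(norm[, 3:4]) + 1))
  expect_equal(lfc_pkg, lfc_hand, tolerance = 1e-8)

  # all-zero region is missing
  z <- rbind(cnts, 0)
  expect_true(is.na(binned_mark_lfc(z[, 1:2], z[, 3:4])[4]))
})

test_that("loop matching requires both anchors and resolves by overlap", {
  l1 <- data.frame(chrom = "c1", start1 = 10000, end1 = 20000,
                   start2 = 210000, end2 = 220000)
  expect_equal(nrow(common_loops(l1, l1)), 1L)

  # anchors offset by 5 kb with 10 kb widths still overlap pairwise
  l2 <- data.frame(chrom = "c1", start1 = 15000, end1 = 25000,
                   start2 = 215000, end2 = 225000)
  m <- common_loops(l1, l2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start1, m$end1), c(10000, 25000))  # union coordinates

  # one disjoint anchor: no match
  l3 <- data.frame(chrom = "c1", start1 = 15000, end1 = 25000,
                   start2 = 400000, end2 = 410000)
  expect_equal(nrow(common_loops(l1, l3)), 0L)

  # multi-match: the larger summed anchor overlap wins
  l4 <- rbind(l1, l2)
  m2 <- common_loops(l4, l1)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$idx_high, 1L)
})

test_that("per-TAD PC1 differences and switch overlaps are measured in bp", {
  grid <- make_bins(c(c1 = 1e6), 5e4)
  trk <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    pc1 = rep(1, nrow(grid)), label = "A")
  tads <- data.frame(chrom = "c1", start = 0, end = 400000)
  sw <- data.frame(chrom = "c1", start = 100000, end = 300000, class = "BA")
  out <- tad_pc1_diff(trk, trk, tads, sw)
  expect_equal(out$pc1_diff, 0)
  expect_equal(out$ba_overlap, 200000)
  expect_equal(out$ab_overlap, 0)

  trk_hi <- trk; trk_hi$pc1 <- 2
  out2 <- tad_pc1_diff(trk_hi, trk, tads, sw)
  expect_equal(out2$pc1_diff, 1)
})

test_that("direction classes partition domains and correlations are Pearson", {
  df <- data.frame(mean_lfc_ctcf = c(1, -1, 1, NA),
                   mean_lfc_k27ac = c(2, -0.5, -1, 1),
                   mean_lfc_rna = c(0.5, -2, 1, 1))
  cs <- correlation_summary(df)
  expect_equal(nrow(cs$table), 3L)  # NA row filtered
  expect_equal(cs$table$class, c("positive", "negative", "none"))
  expect_setequal(unique(cs$table$class) %in%
                    c("positive", "negative", "none"), TRUE)
  expect_equal(unname(cs$correlations["mean_lfc_ctcf", "mean_lfc_ctcf"]), 1)

  perfect <- data.frame(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 6, 9))
  cs2 <- correlation_summary(perfect, features = c("a", "b", "c"))
  expect_equal(unname(cs2$correlations["a", "b"]), 1)
  # fewer than three domains: correlations undefined
  cs3 <- correlation_summary(df[1:2, ])
  expect_null(cs3$correlations)
})

test_that("peaks are classed promoter, distal, or unassigned by TSS distance", {
  genes <- data.frame(chrom = "c1", start = 500000, end = 520000,
                      tss = 500000, strand = "+")
  peaks <- data.frame(chrom = "c1",
                      start = c(499000, 600000, 800500),
                      end = c(499400, 600400, 800900))
  ann <- annotate_peak_gene(peaks, genes)
  expect_equal(ann$peak_class, c("promoter", "distal", "unassigned"))
  expect_equal(ann$associations$class[ann$associations$peak == 2], "distal")
})

test_that("co-planted chromatin and expression changes correlate at TAD level", {
  tr <- simulate_truth(sim_config(n_genes = 2000L), seed = 1)
  ft <- simulate_feature_tables(tr, seed = 2)
  tads <- tr$tads
  mlfc <- function(tab) domain_mean_lfc(
    assign_features_to_domains(tab, tads, "common_tad"), tab, nrow(tads),
    "differential", diff_q = 0.05)
  df <- data.frame(mean_lfc_ctcf = mlfc(ft$peaks$ctcf),
                   mean_lfc_k27ac = mlfc(ft$peaks$h3k27ac),
                   mean_lfc_rna = mlfc(ft$genes))
  cs <- correlation_summary(df)
  expect_gte(nrow(cs$table), 3L)
  expect_true(all(cs$correlations[upper.tri(cs$correlations)] > 0.5))
})
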