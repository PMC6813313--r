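# --- overlap machinery (GenomicRanges joins) ------------------------------

# hits of features vs domains under a rule; returns data.frame(feature, domain)
overlap_join <- function(fs, ds, type = c("any", "within")) {
  type <- match.arg(type)
  h <- GenomicRanges::findOverlaps(as_granges(fs), as_granges(ds),
                                   type = type, minoverlap = 1L)
  data.frame(feature = S4Vectors::queryHits(h),
             domain = S4Vectors::subjectHits(h))
}

overlap_hits <- function(features, domains) {
  if (nrow(features) == 0L || nrow(domains) == 0L)
    return(data.frame(feature = integer(0), domain = integer(0)))
  overlap_join(features, domains, "any")
}

containment_hits <- function(features, domains) {
  if (nrow(features) == 0L || nrow(domains) == 0L)
    return(data.frame(feature = integer(0), domain = integer(0)))
  overlap_join(features, domains, "within")
}

# genes vs domains through the 5 kb upstream-of-TSS promoter window
promoter_hits <- function(genes, domains) {
  if (nrow(genes) == 0L || nrow(domains) == 0L)
    return(data.frame(feature = integer(0), domain = integer(0)))
  w <- promoter_window(genes$tss, genes$strand, width = 5000)
  prom <- data.frame(chrom = genes$chrom, start = w$start, end = w$end)
  overlap_join(prom, domains, "any")
}

#' Assign features to compartment regions, common TADs, or loops
#'
#' Compartment regions and TADs use full containment of the feature;
#' loops use any overlap with the full loop span (anchor1 start to anchor2
#' end), except genes, which use the 5 kb upstream-of-TSS promoter window.
#'
#' @param features Feature table (chrom/start/end; genes need \code{tss} and
#'   \code{strand}).
#' @param domains Domain table; loops need \code{start1}/\code{end2}.
#' @param kind One of \code{"compartment_region"}, \code{"common_tad"},
#'   \code{"loop"}.
#' @param feature_is_gene Use the promoter rule for loop assignment.
#' @return Data frame with \code{feature} and \code{domain} row indices.
#' @export
assign_features_to_domains <- function(features, domains,
                                       kind = c("compartment_region",
                                                "common_tad", "loop"),
                                       feature_is_gene = FALSE) {
  kind <- match.arg(kind)
  if (kind == "loop") {
    span <- data.frame(chrom = domains$chrom, start = domains$start1,
                       end = domains$end2)
    if (feature_is_gene) promoter_hits(features, span)
    else overlap_hits(features, span)
  } else {
    containment_hits(features, domains)
  }
}

#' Per-domain mean log2 fold change
#'
#' Averages the \code{log2fc} of assigned features per domain, either over
#' all features or only the differential subset (q and |log2fc| thresholds).
#' Domains with no qualifying feature get NA and should be filtered before
#' correlation analysis.
#'
#' @param assignment Data frame from [assign_features_to_domains()].
#' @param features The feature table the assignment refers to.
#' @param n_domains Number of domains.
#' @param mode \code{"all"} or \code{"differential"}.
#' @param diff_q,diff_lfc Thresholds for the differential mode.
#' @return Numeric vector (length \code{n_domains}) of mean log2fc.
#' @export
domain_mean_lfc <- function(assignment, features, n_domains,
                            mode = c("all", "differential"),
                            diff_q = 0.05, diff_lfc = 0) {
  mode <- match.arg(mode)
  keep <- assignment
  if (mode == "differential") {
    ok <- features$qvalue[keep$feature] < diff_q &
      abs(features$log2fc[keep$feature]) > diff_lfc
    keep <- keep[ok, , drop = FALSE]
  }
  out <- rep(NA_real_, n_domains)
  if (nrow(keep)) {
    agg <- tapply(features$log2fc[keep$feature], keep$domain, mean)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Normalized log2 fold change of binned mark coverage per region
#'
#' Uses median-of-ratios size factors (computed across all replicates of both
#' conditions) to normalize region counts, then reports the log2 ratio of
#' condition means with a pseudocount of 1. Regions with zero counts
#' everywhere are NA.
#'
#' @param counts_high,counts_low Integer matrices, regions x replicates.
#' @param size_factors Optional per-column size factors (high columns first);
#'   computed from the data when NULL.
#' @return Numeric vector of per-region log2 fold changes.
#' @export
binned_mark_lfc <- function(counts_high, counts_low, size_factors = NULL) {
  cnts <- cbind(counts_high, counts_low)
  if (is.null(size_factors))
    size_factors <- DESeq2::estimateSizeFactorsForMatrix(cnts)
  norm <- sweep(cnts, 2, size_factors, "/")
  nh <- ncol(counts_high)
  mh <- rowMeans(norm[, seq_len(nh), drop = FALSE])
  ml <- rowMeans(norm[, -seq_len(nh), drop = FALSE])
  lfc <- log2((mh + 1) / (ml + 1))
  lfc[rowSums(cnts) == 0] <- NA_real_
  lfc
}

#' Match loops between conditions by anchor overlap
#'
#' Two loops match when anchor1 overlaps anchor1 and anchor2 overlaps anchor2
#' (> 0 bp each). Multiple matches are resolved by the maximal summed anchor
#' overlap. Matched loop coordinates are the union of the anchor pairs.
#'
#' @param loops_high,loops_low Loop tables (chrom/start1/end1/start2/end2).
#' @return Data frame of common loops with union coordinates and the source
#'   row indices \code{idx_high}, \code{idx_low}.
#' @export
common_loops <- function(loops_high, loops_low) {
  a1 <- overlap_hits(
    data.frame(chrom = loops_high$chrom, start = loops_high$start1,
               end = loops_high$end1),
    data.frame(chrom = loops_low$chrom, start = loops_low$start1,
               end = loops_low$end1))
  a2 <- overlap_hits(
    data.frame(chrom = loops_high$chrom, start = loops_high$start2,
               end = loops_high$end2),
    data.frame(chrom = loops_low$chrom, start = loops_low$start2,
               end = loops_low$end2))
  key1 <- paste(a1$feature, a1$domain)
  key2 <- paste(a2$feature, a2$domain)
  both <- a1[key1 %in% key2, , drop = FALSE]
  if (nrow(both) == 0L)
    return(data.frame(chrom = character(0), start1 = numeric(0),
                      end1 = numeric(0), start2 = numeric(0),
                      end2 = numeric(0), idx_high = integer(0),
                      idx_low = integer(0)))
  ov <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2)
  both$overlap <-
    ov(loops_high$start1[both$feature], loops_high$end1[both$feature],
       loops_low$start1[both$domain], loops_low$end1[both$domain]) +
    ov(loops_high$start2[both$feature], loops_high$end2[both$feature],
       loops_low$start2[both$domain], loops_low$end2[both$domain])
  both <- both[order(-both$overlap, both$feature, both$domain), , drop = FALSE]
  usedh <- logical(nrow(loops_high)); usedl <- logical(nrow(loops_low))
  rows <- list()
  for (r in seq_len(nrow(both))) {
    i <- both$feature[r]; j <- both$domain[r]
    if (usedh[i] || usedl[j]) next
    usedh[i] <- TRUE; usedl[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = loops_high$chrom[i],
      start1 = min(loops_high$start1[i], loops_low$start1[j]),
      end1 = max(loops_high$end1[i], loops_low$end1[j]),
      start2 = min(loops_high$start2[i], loops_low$start2[j]),
      end2 = max(loops_high$end2[i], loops_low$end2[j]),
      idx_high = i, idx_low = j)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-TAD PC1 mean difference and switch-region overlap
#'
#' Mean PC1 (compartment-grid bins whose midpoint lies inside the TAD) per
#' condition, difference High minus Low, plus the bp overlap of each TAD with
#' AB and BA switch regions.
#'
#' @param track_high,track_low PC1 tracks from [compute_pc1()].
#' @param common_tads Common TAD table.
#' @param switch_regions Regions from [detect_switching()].
#' @return \code{common_tads} with \code{pc1_high}, \code{pc1_low},
#'   \code{pc1_diff}, \code{ab_overlap}, \code{ba_overlap}.
#' @export
tad_pc1_diff <- function(track_high, track_low, common_tads, switch_regions) {
  out <- common_tads
  mids <- (track_high$start + track_high$end) / 2
  out$pc1_high <- NA_real_; out$pc1_low <- NA_real_
  for (t in seq_len(nrow(out))) {
    sel <- track_high$chrom == out$chrom[t] & mids >= out$start[t] &
      mids < out$end[t]
    if (!any(sel)) next
    out$pc1_high[t] <- mean(track_high$pc1[sel], na.rm = TRUE)
    out$pc1_low[t] <- mean(track_low$pc1[sel], na.rm = TRUE)
  }
  out$pc1_diff <- out$pc1_high - out$pc1_low
  ov_len <- function(cls) {
    reg <- switch_regions[switch_regions$class == cls, , drop = FALSE]
    vapply(seq_len(nrow(out)), function(t) {
      sel <- reg$chrom == out$chrom[t]
      if (!any(sel)) return(0)
      sum(pmax(0, pmin(reg$end[sel], out$end[t]) -
                 pmax(reg$start[sel], out$start[t])))
    }, numeric(1))
  }
  out$ab_overlap <- ov_len("AB")
  out$ba_overlap <- ov_len("BA")
  out
}

#' Direction classes and pairwise correlations across domains
#'
#' Domains with any requested feature missing are filtered. A domain is
#' \code{positive} when every feature mean is > 0, \code{negative} when every
#' one is < 0, otherwise \code{none}. Pairwise Pearson correlations are
#' computed over the filtered domains.
#'
#' @param summaries Data frame of per-domain feature means.
#' @param features Column names to include.
#' @return List with \code{table} (filtered, plus \code{class}) and
#'   \code{correlations} (feature x feature Pearson matrix, NULL when < 3
#'   domains remain).
#' @export
correlation_summary <- function(summaries,
                                features = c("mean_lfc_ctcf",
                                             "mean_lfc_k27ac",
                                             "mean_lfc_rna")) {
  sub <- summaries[stats::complete.cases(summaries[, features, drop = FALSE]),
                   , drop = FALSE]
  m <- as.matrix(sub[, features, drop = FALSE])
  cls <- rep("none", nrow(sub))
  cls[rowSums(m > 0) == length(features)] <- "positive"
  cls[rowSums(m < 0) == length(features)] <- "negative"
  sub$class <- cls
  corr <- if (nrow(sub) >= 3L) stats::cor(m) else NULL
  list(table = sub, correlations = corr)
}

#' Promoter/distal association of peaks with genes
#'
#' A peak overlapping any TSS +/- \code{promoter_halfwidth} window is labeled
#' \code{promoter}; otherwise it is \code{distal}-associated with every gene
#' whose TSS lies within (\code{distal_min}, \code{distal_max}] of the peak;
#' otherwise \code{unassigned}.
#'
#' @param peaks Peak table.
#' @param genes Gene table with \code{tss}.
#' @param promoter_halfwidth,distal_min,distal_max Window parameters in bp.
#' @return List with \code{peak_class} (per peak) and \code{associations}
#'   (peak, gene, class rows).
#' @export
annotate_peak_gene <- function(peaks, genes, promoter_halfwidth = 3000,
                               distal_max = 250000, distal_min = 3000) {
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - promoter_halfwidth),
                     end = genes$tss + promoter_halfwidth)
  ph <- overlap_hits(peaks, prom)
  cls <- rep("unassigned", nrow(peaks))
  cls[unique(ph$feature)] <- "promoter"
  assoc <- if (nrow(ph)) data.frame(peak = ph$feature, gene = ph$domain,
                                    class = "promoter") else
    data.frame(peak = integer(0), gene = integer(0), class = character(0))
  # distal: distance from TSS to the nearest point of the peak
  dwin <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - distal_max),
                     end = genes$tss + distal_max)
  dh <- overlap_hits(peaks, dwin)
  if (nrow(dh)) {
    tss <- genes$tss[dh$domain]
    d <- pmax(peaks$start[dh$feature] - tss, tss - peaks$end[dh$feature], 0)
    keep <- cls[dh$feature] != "promoter" & d > distal_min & d <= distal_max
    if (any(keep)) {
      cls[unique(dh$feature[keep])] <- "distal"
      assoc <- rbind(assoc, data.frame(peak = dh$feature[keep],
                                       gene = dh$domain[keep],
                                       class = "distal"))
    }
  }
  list(peak_class = cls, associations = assoc)
}
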