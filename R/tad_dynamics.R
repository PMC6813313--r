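#' Identify common TADs between two samples
#'
#' TADs shorter than \code{min_bins} are dropped. After extending candidate
#' TADs by \code{extension_bins} on either side for matching, two TADs are
#' positionally consistent when both boundaries lie within \code{slack_bins}
#' bins of each other. A matched pair yields one common TAD whose boundaries
#' are set to those that yield the largest TAD. A TAD matching several
#' partners is resolved by the smallest summed boundary distance, ties by the
#' leftmost interval; the result is symmetric in argument order.
#'
#' @param tads1,tads2 TAD tables (chrom/start/end), non-overlapping within
#'   each sample.
#' @param bin_size Bin size in bp.
#' @param min_bins Minimum TAD length in bins.
#' @param extension_bins Per-side search extension in bins.
#' @param slack_bins Maximum per-boundary offset in bins.
#' @return Data frame of common TADs with source intervals.
#' @export
find_common_tads <- function(tads1, tads2, bin_size, min_bins = 10L,
                             extension_bins = 3L, slack_bins = 3L) {
  keep1 <- tads1[(tads1$end - tads1$start) >= min_bins * bin_size, ,
                 drop = FALSE]
  keep2 <- tads2[(tads2$end - tads2$start) >= min_bins * bin_size, ,
                 drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), start1 = numeric(0),
                      end1 = numeric(0), start2 = numeric(0),
                      end2 = numeric(0))
  if (nrow(keep1) == 0L || nrow(keep2) == 0L) return(empty)
  slack <- slack_bins * bin_size
  ext <- extension_bins * bin_size
  cand <- list()
  for (i in seq_len(nrow(keep1))) {
    # extension bounds the candidate search; the slack rule decides the match
    near <- which(keep2$chrom == keep1$chrom[i] &
                    keep2$start >= keep1$start[i] - ext - slack &
                    keep2$end <= keep1$end[i] + ext + slack &
                    abs(keep2$start - keep1$start[i]) <= slack &
                    abs(keep2$end - keep1$end[i]) <= slack)
    for (j in near) {
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j,
        dist = abs(keep2$start[j] - keep1$start[i]) +
          abs(keep2$end[j] - keep1$end[i]),
        left = min(keep1$start[i], keep2$start[j]))
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, cand$left, cand$i, cand$j), , drop = FALSE]
  used1 <- logical(nrow(keep1)); used2 <- logical(nrow(keep2))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = keep1$chrom[i],
      start = min(keep1$start[i], keep2$start[j]),
      end = max(keep1$end[i], keep2$end[j]),
      start1 = keep1$start[i], end1 = keep1$end[i],
      start2 = keep2$start[j], end2 = keep2$end[j])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$tad_id <- sprintf("ctad%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Intra-TAD interaction change between two samples
#'
#' For each common TAD, takes all intra-TAD bin pairs (i <= j, both bins
#' unmasked in both samples) and computes the difference of mean interaction
#' intensities, sample 2 minus sample 1, together with a paired two-sided
#' t-test over the per-pair differences. Both matrices must be balanced and
#' scaled to a common total. FDR (BH) is applied across TADs.
#'
#' @param cm1,cm2 Balanced, total-scaled \code{contact_matrix} objects on the
#'   same grid.
#' @param common_tads Output of [find_common_tads()].
#' @return \code{common_tads} augmented with \code{n_pairs}, \code{s1_mean},
#'   \code{s2_mean}, \code{change}, \code{pvalue}, \code{qvalue},
#'   \code{testable}.
#' @export
intra_tad_change <- function(cm1, cm2, common_tads) {
  bins <- cm1$bins
  out <- common_tads
  nt <- nrow(out)
  out$n_pairs <- 0L
  out$s1_mean <- NA_real_; out$s2_mean <- NA_real_
  out$change <- NA_real_; out$pvalue <- NA_real_
  out$testable <- FALSE
  for (t in seq_len(nt)) {
    idx <- which(bins$chrom == out$chrom[t] & bins$start >= out$start[t] &
                   bins$end <= out$end[t] & !cm1$mask & !cm2$mask)
    if (length(idx) < 2L) next
    ut <- upper.tri(matrix(0, length(idx), length(idx)), diag = TRUE)
    s1 <- cm1$counts[idx, idx][ut]
    s2 <- cm2$counts[idx, idx][ut]
    out$n_pairs[t] <- length(s1)
    out$s1_mean[t] <- mean(s1)
    out$s2_mean[t] <- mean(s2)
    out$change[t] <- mean(s2) - mean(s1)
    if (length(s1) < 3L) next
    out$testable[t] <- TRUE
    d <- s2 - s1
    out$pvalue[t] <- if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      stats::t.test(s2, s1, paired = TRUE)$p.value
    }
  }
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out
}

#' Classify intra-TAD interaction changes
#'
#' Gain when \code{change > min_abs_change} and \code{qvalue < fdr}; Loss for
#' the mirrored condition; otherwise Stable.
#'
#' @param results Output of [intra_tad_change()].
#' @param fdr FDR threshold.
#' @param min_abs_change Minimum absolute change.
#' @return \code{results} with a \code{class} column.
#' @export
classify_intra_tad <- function(results, fdr = 0.1, min_abs_change = 0.3) {
  cls <- rep("Stable", nrow(results))
  sig <- !is.na(results$qvalue) & results$qvalue < fdr
  cls[sig & results$change > min_abs_change] <- "Gain"
  cls[sig & results$change < -min_abs_change] <- "Loss"
  results$class <- cls
  results
}
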