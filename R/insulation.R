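#' Ratio insulation score per bin
#'
#' For bin \code{i} with window \code{w} bins, let L be the total contact
#' count among bins \code{[i-w, i]}, R the total among \code{[i, i+w]} and X
#' the total between \code{[i-w, i-1]} and \code{[i+1, i+w]} (cross-bin
#' contacts). The score is \code{(L + R + 1) / (2 X + 1)}; higher means
#' stronger insulation. Bins without full flanks are NA.
#'
#' Masked bins get NA scores. Window sums near masked bins are rescaled by
#' the fraction of valid (unmasked) bin pairs they cover, so that zeroed
#' rows do not fake insulation; bins whose windows retain fewer than
#' \code{min_valid_frac} valid pairs are NA.
#'
#' @param cm A balanced \code{contact_matrix}.
#' @param window_bins Insulation window in bins; the default corresponds to
#'   500 kb at the matrix resolution.
#' @param min_valid_frac Minimum fraction of unmasked pairs per window
#'   region.
#' @return Numeric vector of scores, one per bin of \code{cm$bins} (class
#'   \code{insulation_track}).
#' @export
ratio_insulation <- function(cm, window_bins = NULL, min_valid_frac = 0.5) {
  bs <- bin_size_of(cm$bins)
  if (is.null(window_bins)) window_bins <- max(1L, floor(5e5 / bs))
  w <- as.integer(window_bins)
  if (w < 1L) stop("window_bins must be >= 1")
  M <- cm$counts
  score <- rep(NA_real_, nrow(cm$bins))
  for (idx in chrom_blocks(cm$bins)) {
    n <- length(idx)
    if (n < 2L * w + 1L) {
      warning("insulation window larger than chromosome; track left missing")
      next
    }
    sub <- M[idx, idx, drop = FALSE]
    ok <- !cm$mask[idx]
    tri_stat <- function(i0, i1) {
      b <- i0:i1
      Bm <- sub[b, b, drop = FALSE]
      ut <- upper.tri(Bm, diag = TRUE)
      valid <- outer(ok[b], ok[b], "&")[ut]
      c(sum(Bm[ut]), sum(valid), length(valid))
    }
    for (i in (w + 1L):(n - w)) {
      if (!ok[i]) next
      sl <- tri_stat(i - w, i)
      sr <- tri_stat(i, i + w)
      li <- (i - w):(i - 1L); ri <- (i + 1L):(i + w)
      xb <- sub[li, ri, drop = FALSE]
      xv <- outer(ok[li], ok[ri], "&")
      sx <- c(sum(xb), sum(xv), length(xv))
      fr <- c(sl[2] / sl[3], sr[2] / sr[3], sx[2] / sx[3])
      if (any(fr < min_valid_frac)) next
      L <- sl[1] / fr[1]
      R <- sr[1] / fr[2]
      X <- sx[1] / fr[3]
      score[idx[i]] <- (L + R + 1) / (2 * X + 1)
    }
  }
  structure(score, class = "insulation_track", window_bins = w)
}

#' Call TADs and boundaries from an insulation track
#'
#' Works on a per-condition merged ("by group") track. Boundary regions are
#' maximal contiguous runs of bins with score at or above the chromosome mean
#' that contain at least one local maximum exceeding mean + k*sd. TADs span
#' between the peak centers (maximum-score bins) of consecutive boundaries,
#' so that adjacent TADs abut at the point of strongest insulation; the
#' chromosome-end segments are included.
#'
#' @param track Insulation track from [ratio_insulation()].
#' @param bins The matching \code{bin_table}.
#' @param k Peak threshold in standard deviations above the chromosome mean.
#' @return List with \code{boundaries} (chrom/start/end/bin_count/center/
#'   max_score/mean_score) and \code{tads} (chrom/start/end) data frames.
#' @export
call_tads_and_boundaries <- function(track, bins, k = 0.5) {
  bounds <- list(); tads <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    sc <- track[idx]
    ok <- !is.na(sc)
    if (!any(ok)) next
    m <- mean(sc[ok]); s <- stats::sd(sc[ok])
    if (!is.finite(s) || s == 0) {
      tads[[ch]] <- data.frame(chrom = ch, start = bins$start[idx[1]],
                               end = bins$end[idx[length(idx)]])
      next
    }
    above <- ok & sc >= m
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    breg <- data.frame()
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      if (max(sc[a:b]) > m + k * s) {
        pk <- a + which.max(sc[a:b]) - 1L
        breg <- rbind(breg, data.frame(
          chrom = ch, start = bins$start[idx[a]], end = bins$end[idx[b]],
          bin_count = b - a + 1L, center = bins$start[idx[pk]],
          max_score = max(sc[a:b]), mean_score = mean(sc[a:b])))
      }
    }
    chrom_start <- bins$start[idx[1]]
    chrom_end <- bins$end[idx[length(idx)]]
    if (nrow(breg) == 0L) {
      tads[[ch]] <- data.frame(chrom = ch, start = chrom_start,
                               end = chrom_end)
      next
    }
    bounds[[ch]] <- breg
    cuts <- breg$center
    ts <- c(chrom_start, cuts)
    te <- c(cuts, chrom_end)
    keep <- te > ts
    tads[[ch]] <- data.frame(chrom = ch, start = ts[keep], end = te[keep])
  }
  boundaries <- if (length(bounds)) do.call(rbind, bounds) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               bin_count = integer(0), center = numeric(0),
               max_score = numeric(0), mean_score = numeric(0))
  taddf <- if (length(tads)) do.call(rbind, tads) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(boundaries) <- rownames(taddf) <- NULL
  list(boundaries = boundaries, tads = taddf)
}

#' Boundary span in bp
#' @param bin_count Number of bins in the boundary region.
#' @param bin_size Bin size in bp.
#' @export
boundary_size <- function(bin_count, bin_size) {
  stopifnot(all(bin_count >= 1))
  bin_count * bin_size
}

#' Mean boundary score (MBS)
#'
#' Arithmetic mean of the per-bin ratio insulation scores inside a boundary
#' region.
#'
#' @param track Insulation track.
#' @param bins Matching \code{bin_table}.
#' @param boundary One-row data frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @return Mean score, or NA when no covered bins.
#' @export
mean_boundary_score <- function(track, bins, boundary) {
  idx <- which(bins$chrom == boundary$chrom &
                 bins$start >= boundary$start & bins$end <= boundary$end)
  sc <- track[idx]
  if (!length(sc) || all(is.na(sc))) return(NA_real_)
  mean(sc, na.rm = TRUE)
}

boundary_bin_idx <- function(bins, boundaries) {
  lapply(seq_len(nrow(boundaries)), function(b) {
    which(bins$chrom == boundaries$chrom[b] &
            bins$start >= boundaries$start[b] &
            bins$end <= boundaries$end[b])
  })
}

#' Differential boundary insulation analysis
#'
#' For every reference boundary, pools the per-bin, per-replicate ratio
#' insulation scores by condition, applies a two-sided unpaired (pooled
#' variance) t-test, computes the MBS log2 fold change of condition means,
#' and adjusts across boundaries with Benjamini-Hochberg.
#'
#' @param tracks_high,tracks_low Lists of per-replicate insulation tracks.
#' @param reference_boundaries Boundary regions (normally called from the
#'   reference/low condition).
#' @param bins Matching \code{bin_table}.
#' @param lfc_threshold,q_threshold Significance thresholds on
#'   \code{|mbs_log2fc|} and FDR for the \code{significant} flag.
#' @return \code{reference_boundaries} augmented with \code{mbs_high},
#'   \code{mbs_low}, \code{mbs_log2fc}, \code{pvalue}, \code{qvalue},
#'   \code{significant}.
#' @export
differential_boundaries <- function(tracks_high, tracks_low,
                                    reference_boundaries, bins,
                                    lfc_threshold = 0.1, q_threshold = 0.05) {
  stopifnot(length(tracks_high) >= 1, length(tracks_low) >= 1)
  out <- reference_boundaries
  nb <- nrow(out)
  idxs <- boundary_bin_idx(bins, out)
  res <- vapply(seq_len(nb), function(b) {
    idx <- idxs[[b]]
    hi <- unlist(lapply(tracks_high, function(tr) tr[idx]))
    lo <- unlist(lapply(tracks_low, function(tr) tr[idx]))
    hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
    if (!length(hi) || !length(lo))
      return(c(NA_real_, NA_real_, NA_real_))
    p <- if (length(hi) < 2L || length(lo) < 2L) {
      NA_real_
    } else if (stats::sd(hi) == 0 && stats::sd(lo) == 0) {
      warning("zero-variance score pool; p set to 1")
      1
    } else {
      stats::t.test(hi, lo, var.equal = TRUE)$p.value
    }
    c(mean(hi), mean(lo), p)
  }, numeric(3))
  out$mbs_high <- res[1, ]
  out$mbs_low <- res[2, ]
  out$mbs_log2fc <- log2(out$mbs_high / out$mbs_low)
  out$pvalue <- res[3, ]
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- !is.na(out$qvalue) & out$qvalue < q_threshold &
    abs(out$mbs_log2fc) > lfc_threshold
  out
}

#' Peak occupancy within (extended) boundary regions
#'
#' Assigns peaks to boundaries by any overlap (> 0 bp) with the boundary
#' region extended by \code{extension_bins} bins on either side, aggregates
#' the assigned peak intensities per replicate, and tests condition
#' differences by a two-sided unpaired t-test pooling all assigned peak
#' intensities. BH correction is applied across boundaries.
#'
#' @param peaks Peak table with per-replicate intensity columns
#'   \code{high_*} / \code{low_*}.
#' @param boundaries Boundary regions.
#' @param bin_size Bin size in bp used for the extension.
#' @param extension_bins Number of bins to extend on each side.
#' @return \code{boundaries} augmented with \code{n_peaks}, per-replicate
#'   aggregate columns, \code{occ_log2fc}, \code{occ_pvalue},
#'   \code{occ_qvalue}.
#' @export
boundary_occupancy <- function(peaks, boundaries, bin_size,
                               extension_bins = 1L) {
  ext <- extension_bins * bin_size
  reg <- boundaries
  reg$start <- pmax(0, boundaries$start - ext)
  reg$end <- boundaries$end + ext
  hits <- overlap_hits(peaks, reg)
  hi_cols <- grep("^high_", names(peaks), value = TRUE)
  lo_cols <- grep("^low_", names(peaks), value = TRUE)
  nb <- nrow(boundaries)
  out <- boundaries
  out$n_peaks <- 0L
  out$occ_high <- NA_real_; out$occ_low <- NA_real_
  out$occ_log2fc <- NA_real_; out$occ_pvalue <- NA_real_
  for (b in seq_len(nb)) {
    pk <- hits$feature[hits$domain == b]
    out$n_peaks[b] <- length(pk)
    if (!length(pk)) next
    hi <- as.matrix(peaks[pk, hi_cols, drop = FALSE])
    lo <- as.matrix(peaks[pk, lo_cols, drop = FALSE])
    out$occ_high[b] <- mean(colSums(hi))
    out$occ_low[b] <- mean(colSums(lo))
    out$occ_log2fc[b] <- log2(out$occ_high[b] / out$occ_low[b])
    ph <- as.vector(hi); pl <- as.vector(lo)
    out$occ_pvalue[b] <- if (length(ph) < 2L || length(pl) < 2L) NA_real_
      else if (stats::sd(ph) == 0 && stats::sd(pl) == 0) 1
      else stats::t.test(ph, pl, var.equal = TRUE)$p.value
  }
  out$occ_qvalue <- stats::p.adjust(out$occ_pvalue, method = "BH")
  out
}
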