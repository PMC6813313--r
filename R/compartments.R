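#' A/B compartment eigenvector (PC1) with active-mark orientation
#'
#' Per chromosome: observed/expected transform, Pearson correlation matrix
#' over unmasked bins, first eigenvector. The sign is oriented so that bins
#' containing at least one active-mark peak (H3K27ac) have positive mean PC1.
#' Label A means PC1 > 0, B means PC1 < 0 (masked bins are labeled
#' \code{"masked"}).
#'
#' @param cm A balanced \code{contact_matrix} (compartment resolution,
#'   typically 50 kb).
#' @param active_peaks Peak table (chrom/start/end) of the active mark.
#' @return Data frame: one row per bin with \code{pc1} and \code{label}.
#' @export
compute_pc1 <- function(cm, active_peaks) {
  if (is.null(active_peaks) || nrow(active_peaks) == 0L)
    stop("active_peaks must be nonempty for sign orientation")
  bins <- cm$bins
  oe_all <- observed_over_expected(cm)
  pc1 <- rep(NA_real_, nrow(bins))
  for (ch in names(oe_all)) {
    blk <- oe_all[[ch]]
    keep <- which(!blk$mask)
    if (length(keep) <= 2L) {
      warning("chromosome ", ch, " skipped: too few unmasked bins")
      next
    }
    oe <- blk$oe[keep, keep, drop = FALSE]
    C <- suppressWarnings(stats::cor(oe, use = "pairwise.complete.obs"))
    bad <- apply(C, 2, function(x) any(!is.finite(x)))
    if (any(bad)) {
      keep <- keep[!bad]
      C <- C[!bad, !bad, drop = FALSE]
    }
    if (length(keep) <= 2L) next
    eg <- eigen(C, symmetric = TRUE)
    v <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
    pc1[blk$bins_idx[keep]] <- v
  }
  # orientation: bins holding >= 1 active peak must average positive
  hit <- overlap_hits(active_peaks, bins)
  act <- unique(hit$domain)
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    a <- intersect(act, idx)
    if (length(a) && !all(is.na(pc1[a])) &&
        mean(pc1[a], na.rm = TRUE) < 0)
      pc1[idx] <- -pc1[idx]
  }
  label <- ifelse(is.na(pc1), "masked", ifelse(pc1 > 0, "A", "B"))
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             pc1 = pc1, label = label, stringsAsFactors = FALSE)
}

#' Detect compartment switching between conditions
#'
#' Per bin, the Pearson correlation between its cis interaction-profile rows
#' (observed/expected) in the two conditions is computed. A bin switches when
#' its PC1 sign differs between conditions and the profile correlation is
#' below \code{corr_threshold}. Adjacent bins of the same class are merged
#' into regions; AB means A (low) to B (high), BA the reverse.
#'
#' @param track_high,track_low PC1 tracks from [compute_pc1()] on the same
#'   grid.
#' @param cm_high,cm_low Balanced matrices for the two conditions.
#' @param corr_threshold Correlation below which a sign flip counts as a
#'   switch.
#' @return Data frame of regions with \code{class} (AB/BA/Stable) and mean
#'   profile correlation.
#' @export
detect_switching <- function(track_high, track_low, cm_high, cm_low,
                             corr_threshold = 0.4) {
  stopifnot(nrow(track_high) == nrow(track_low))
  bins <- cm_high$bins
  oe_h <- observed_over_expected(cm_high)
  oe_l <- observed_over_expected(cm_low)
  n <- nrow(bins)
  corr <- rep(NA_real_, n)
  for (ch in names(oe_h)) {
    bh <- oe_h[[ch]]; bl <- oe_l[[ch]]
    keep <- which(!bh$mask & !bl$mask)
    for (i in keep) {
      x <- bh$oe[i, keep]; y <- bl$oe[i, keep]
      drop_self <- keep != i
      ok <- is.finite(x) & is.finite(y) & drop_self
      if (sum(ok) >= 3L)
        corr[bh$bins_idx[i]] <- suppressWarnings(
          stats::cor(x[ok], y[ok]))
    }
  }
  lab_h <- track_high$label
  lab_l <- track_low$label
  cls <- rep("Stable", n)
  flip <- lab_h %in% c("A", "B") & lab_l %in% c("A", "B") & lab_h != lab_l &
    !is.na(corr) & corr < corr_threshold
  cls[flip & lab_l == "A"] <- "AB"
  cls[flip & lab_l == "B"] <- "BA"
  # merge adjacent bins of the same class into regions, per chromosome
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    r <- rle(cls[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    out[[ch]] <- data.frame(
      chrom = ch,
      start = bins$start[idx[starts]],
      end = bins$end[idx[ends]],
      class = r$values,
      mean_corr = vapply(seq_along(r$values), function(k)
        mean(corr[idx[starts[k]:ends[k]]], na.rm = TRUE), numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Saddle matrix over ranked PC1 groups
#'
#' Unmasked bins are sorted by ascending PC1 (strongest B-like to strongest
#' A-like) and split into \code{n_groups} as-equal-as-possible ranks. Entry
#' (g, h) is the log2 of the mean observed/expected value over all bin pairs
#' in g x h (self-pairs excluded). Corner aggregates average the linear-scale
#' block means over the extreme 20\% of ranks: AA (top-top), BB
#' (bottom-bottom), AB/BA (off corners).
#'
#' @param pc1 PC1 track from [compute_pc1()] (pooled replicates).
#' @param cm Balanced \code{contact_matrix} on the same grid.
#' @param n_groups Number of ranks (default 50).
#' @return List of class \code{saddle_result}: \code{saddle} (log2 matrix),
#'   \code{linear} (block means), corner aggregates \code{AA}, \code{BB},
#'   \code{AB}, \code{BA}.
#' @export
saddle_matrix <- function(pc1, cm, n_groups = 50L) {
  oe_all <- observed_over_expected(cm)
  vals <- pc1$pc1
  keep <- which(!is.na(vals))
  if (length(keep) < n_groups)
    stop("fewer unmasked bins than saddle groups")
  ord <- keep[order(vals[keep])]
  m <- length(ord)
  sizes <- rep(m %/% n_groups, n_groups)
  extra <- m %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(n_groups), sizes)
  group_of <- stats::setNames(grp, ord)

  lin <- matrix(NA_real_, n_groups, n_groups)
  sums <- matrix(0, n_groups, n_groups)
  cnts <- matrix(0, n_groups, n_groups)
  for (ch in names(oe_all)) {
    blk <- oe_all[[ch]]
    in_ch <- blk$bins_idx %in% ord
    if (!any(in_ch)) next
    loc <- which(in_ch)
    gl <- group_of[as.character(blk$bins_idx[loc])]
    oe <- blk$oe[loc, loc, drop = FALSE]
    diag(oe) <- NA_real_  # exclude self-pairs
    for (g in seq_len(n_groups)) {
      gi <- which(gl == g)
      if (!length(gi)) next
      for (h in g:n_groups) {
        hi <- which(gl == h)
        if (!length(hi)) next
        v <- oe[gi, hi, drop = FALSE]
        sums[g, h] <- sums[g, h] + sum(v, na.rm = TRUE)
        cnts[g, h] <- cnts[g, h] + sum(is.finite(v))
      }
    }
  }
  ok <- cnts > 0
  lin[ok] <- sums[ok] / cnts[ok]
  lin[lower.tri(lin)] <- t(lin)[lower.tri(lin)]
  corner <- max(1L, round(0.2 * n_groups))
  top <- seq(n_groups - corner + 1L, n_groups)   # strongest A
  bottom <- seq_len(corner)                      # strongest B
  AA <- mean(lin[top, top], na.rm = TRUE)
  BB <- mean(lin[bottom, bottom], na.rm = TRUE)
  AB <- mean(lin[top, bottom], na.rm = TRUE)
  BA <- mean(lin[bottom, top], na.rm = TRUE)
  structure(list(saddle = log2(lin), linear = lin, group_sizes = sizes,
                 AA = AA, BB = BB, AB = AB, BA = BA,
                 corner_values = list(
                   same = c(lin[top, top], lin[bottom, bottom]),
                   cross = c(lin[top, bottom], lin[bottom, top])),
                 n_groups = n_groups, corner = corner),
            class = "saddle_result")
}

#' Compartmentalization strength metrics
#'
#' Both metrics are computed on the linear observed/expected scale from the
#' saddle corners (strongest 20\% of ranks): \code{sqrt(AA * BB / AB^2)} and
#' \code{median(AA u BB) / median(AB u BA)}.
#'
#' @param saddle A \code{saddle_result}.
#' @return List with \code{strength_schwarzer} and \code{strength_nora}.
#' @export
compartment_strength <- function(saddle) {
  if (!is.finite(saddle$AB) || saddle$AB == 0) {
    warning("AB corner undefined or zero; strength undefined")
    return(list(strength_schwarzer = NA_real_, strength_nora = NA_real_))
  }
  sw <- sqrt(saddle$AA * saddle$BB / saddle$AB^2)
  nora <- stats::median(saddle$corner_values$same, na.rm = TRUE) /
    stats::median(saddle$corner_values$cross, na.rm = TRUE)
  list(strength_schwarzer = sw, strength_nora = nora)
}
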