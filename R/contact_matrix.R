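#' Binned contact matrix container
#'
#' A dense symmetric matrix of intra-chromosomal contact counts over a bin
#' grid, with an optional multiplicative bias vector and bin mask produced by
#' ICE balancing. Trans (cross-chromosome) entries are permitted in the
#' container but all analyses in this package are cis-only.
#'
#' @param bins A \code{bin_table}.
#' @param counts Symmetric nonnegative numeric matrix, \code{nrow(bins)} on a
#'   side.
#' @param bias Optional per-bin positive bias (NA for masked bins).
#' @param mask Logical vector, TRUE for masked (excluded) bins.
#' @param normalized Logical, TRUE once balanced.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(bins, counts, bias = NULL, mask = NULL,
                           normalized = FALSE) {
  n <- nrow(bins)
  if (!is.matrix(counts) || nrow(counts) != n || ncol(counts) != n)
    stop("counts must be an n x n matrix matching the bin table")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric")
  if (is.null(mask)) mask <- rep(FALSE, n)
  structure(list(bins = bins, counts = counts, bias = bias, mask = mask,
                 normalized = normalized),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins (%s bp), total %.4g, %d masked, %s\n",
    nrow(x$bins), format(bin_size_of(x$bins), big.mark = ","),
    matrix_total(x), sum(x$mask),
    if (isTRUE(x$normalized)) "balanced" else "raw"))
  invisible(x)
}

#' Total contact count (upper triangle plus diagonal counted once)
#' @param cm A \code{contact_matrix}.
#' @export
matrix_total <- function(cm) {
  sum(cm$counts[upper.tri(cm$counts, diag = TRUE)])
}

# row indices of bins per chromosome, in grid order
chrom_blocks <- function(bins) {
  split(seq_len(nrow(bins)), factor(bins$chrom, levels = unique(bins$chrom)))
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Masks zero-coverage bins plus the lowest \code{mask_low_frac} of
#' nonzero-coverage bins, then iteratively rescales rows and columns by the
#' marginal until all unmasked marginals agree to within \code{tol}
#' (relative). The balanced matrix is rescaled to the original unmasked total
#' so that downstream absolute-intensity statistics remain comparable across
#' samples after [scale_to_total()].
#'
#' @param cm A \code{contact_matrix} with raw counts.
#' @param tol Convergence tolerance on the maximum relative marginal
#'   deviation.
#' @param max_iter Maximum number of iterations.
#' @param mask_low_frac Fraction of lowest-coverage (nonzero) bins to mask.
#' @param mask Optional predefined logical mask (e.g. the union of
#'   per-sample masks from [ice_mask()] when samples will be compared);
#'   zero-coverage bins are always masked in addition.
#' @return A balanced \code{contact_matrix} with \code{bias} and \code{mask}
#'   filled in; masked rows/columns are zeroed.
#' @export
ice_normalize <- function(cm, tol = 1e-5, max_iter = 200L,
                          mask_low_frac = 0.02, mask = NULL) {
  M <- cm$counts
  n <- nrow(M)
  if (is.null(mask)) {
    mask <- ice_mask(cm, mask_low_frac)
  } else {
    stopifnot(length(mask) == n)
    mask <- mask | rowSums(M) <= 0
  }
  if (all(mask)) stop("matrix empty after masking")
  keep <- which(!mask)
  W <- M[keep, keep, drop = FALSE]
  total0 <- sum(W[upper.tri(W, diag = TRUE)])
  if (total0 <= 0) stop("matrix empty after masking")
  b <- rep(1, length(keep))
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    s <- s / mean(s)
    s[s == 0] <- 1
    b <- b * s
    W <- W / outer(s, s)
    if (max(abs(s - 1)) < tol) break
  }
  # restore the original unmasked total
  tot <- sum(W[upper.tri(W, diag = TRUE)])
  W <- W * (total0 / tot)
  out <- matrix(0, n, n)
  out[keep, keep] <- W
  bias <- rep(NA_real_, n)
  bias[keep] <- b
  contact_matrix(cm$bins, out, bias = bias, mask = mask, normalized = TRUE)
}

#' Coverage-based bin mask for ICE balancing
#'
#' Zero-coverage bins plus the lowest \code{mask_low_frac} of
#' nonzero-coverage bins. When two samples are to be compared bin-by-bin
#' (intra-TAD change, differential insulation), balance both with the union
#' of their masks so that bias estimation is comparable.
#'
#' @param cm A raw \code{contact_matrix}.
#' @param mask_low_frac Fraction of lowest-coverage (nonzero) bins to mask.
#' @return Logical vector, TRUE for masked bins.
#' @export
ice_mask <- function(cm, mask_low_frac = 0.02) {
  cov <- rowSums(cm$counts)
  mask <- cov <= 0
  nz <- which(!mask)
  k <- floor(mask_low_frac * length(nz))
  if (k > 0) {
    ord <- nz[order(cov[nz])]
    mask[ord[seq_len(k)]] <- TRUE
  }
  mask
}

#' Scale a contact matrix to a target total count
#'
#' Multiplies every entry by \code{target_total / matrix_total(cm)} so that
#' absolute intensities are comparable across samples; relative structure is
#' unchanged.
#'
#' @param cm A \code{contact_matrix}.
#' @param target_total Positive target for the upper-triangle total.
#' @export
scale_to_total <- function(cm, target_total = 1e6) {
  if (target_total <= 0) stop("target_total must be positive")
  tot <- matrix_total(cm)
  if (tot <= 0) stop("cannot scale an all-zero matrix")
  cm$counts <- cm$counts * (target_total / tot)
  cm
}

#' Distance-decay expected profile
#'
#' Per chromosome, the arithmetic mean contact count over unmasked bin pairs
#' at each separation (in bins). Strata with no unmasked pairs are NA.
#'
#' @param cm A \code{contact_matrix} (normally balanced).
#' @return Named list per chromosome of numeric vectors indexed by distance
#'   \code{0..n-1}.
#' @export
decay_profile <- function(cm) {
  blocks <- chrom_blocks(cm$bins)
  lapply(blocks, function(idx) {
    sub <- cm$counts[idx, idx, drop = FALSE]
    keep <- !cm$mask[idx]
    n <- length(idx)
    out <- rep(NA_real_, n)
    for (s in 0:(n - 1L)) {
      i <- seq_len(n - s)
      ok <- keep[i] & keep[i + s]
      if (any(ok)) out[s + 1L] <- mean(sub[cbind(i[ok], i[ok] + s)])
    }
    out
  })
}

#' Observed/expected transform
#'
#' Divides each cis entry by the decay-profile expectation at its distance.
#' Masked bins and empty strata yield NA (missing), never zero.
#'
#' @param cm A balanced \code{contact_matrix}.
#' @return List per chromosome with elements \code{oe} (matrix with NAs),
#'   \code{bins_idx} (rows of \code{cm$bins}) and \code{mask}.
#' @export
observed_over_expected <- function(cm) {
  blocks <- chrom_blocks(cm$bins)
  expd <- decay_profile(cm)
  out <- lapply(names(blocks), function(ch) {
    idx <- blocks[[ch]]
    sub <- cm$counts[idx, idx, drop = FALSE]
    n <- length(idx)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- matrix(expd[[ch]][d + 1L], n, n)
    oe <- sub / E
    oe[E == 0 | is.na(E)] <- NA_real_
    msk <- cm$mask[idx]
    oe[msk, ] <- NA_real_
    oe[, msk] <- NA_real_
    list(oe = oe, bins_idx = idx, mask = msk)
  })
  names(out) <- names(blocks)
  out
}

#' Sum replicate contact matrices ("by group" merge)
#'
#' @param cms List of \code{contact_matrix} objects on the same bin grid.
#' @return A raw \code{contact_matrix} with summed counts.
#' @export
merge_matrices <- function(cms) {
  stopifnot(length(cms) >= 1)
  M <- Reduce(`+`, lapply(cms, function(x) x$counts))
  contact_matrix(cms[[1]]$bins, M)
}
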