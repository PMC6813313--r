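#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-size bins (0-based, half-open). The last
#' bin of a chromosome is truncated to the chromosome end. Bins carry a dense,
#' ascending 0-based \code{index} across chromosomes, matching the sparse
#' contact-matrix triplet format.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @return A \code{data.frame} of class \code{bin_table} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{index}, and attributes
#'   \code{bin_size} and \code{chrom_sizes}.
#' @examples
#' make_bins(c(chr1 = 190000), 40000)
#' @export
make_bins <- function(chrom_sizes, bin_size) {
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome lengths must be positive")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- as.numeric(bin_size)
  attr(bins, "chrom_sizes") <- chrom_sizes
  class(bins) <- c("bin_table", "data.frame")
  bins
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins of %s bp over %d chromosome(s)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- max(bins$end - bins$start)
  bs
}

#' Map positions to bin indices
#'
#' @param bins A \code{bin_table}.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return 0-based global bin indices (NA when off the grid).
#' @export
bin_at <- function(bins, chrom, pos) {
  bs <- bin_size_of(bins)
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- bins[bins$chrom == ch, ]
    if (nrow(sub) == 0L) next
    k <- floor(pos[sel] / bs)
    ok <- !is.na(k) & k >= 0 & k < nrow(sub)
    idx <- rep(NA_integer_, sum(sel))
    idx[ok] <- sub$index[k[ok] + 1L]
    out[sel] <- idx
  }
  out
}

#' Test whether features belong to domains under a named assignment rule
#'
#' Element-wise comparison of a feature interval against a domain interval.
#' \code{full_containment} requires the feature to lie entirely inside the
#' domain; \code{any_overlap} requires > 0 bp overlap; and
#' \code{promoter_upstream_5kb} tests overlap of the 5 kb window upstream of
#' the TSS (the window's downstream end is the TSS itself, respecting strand)
#' with the domain. Different chromosomes never match.
#'
#' @param feature,domain Data frames with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open); \code{feature} additionally needs
#'   \code{tss} and \code{strand} for the promoter rule. Rows are recycled to
#'   a common length.
#' @param rule One of \code{"full_containment"}, \code{"any_overlap"},
#'   \code{"promoter_upstream_5kb"}.
#' @return Logical vector.
#' @export
interval_assigned <- function(feature, domain,
                              rule = c("full_containment", "any_overlap",
                                       "promoter_upstream_5kb")) {
  rule <- match.arg(rule)
  n <- max(nrow(feature), nrow(domain))
  f <- feature[rep_len(seq_len(nrow(feature)), n), , drop = FALSE]
  d <- domain[rep_len(seq_len(nrow(domain)), n), , drop = FALSE]
  same <- as.character(f$chrom) == as.character(d$chrom)
  if (rule == "promoter_upstream_5kb") {
    w <- promoter_window(f$tss, f$strand, width = 5000)
    fs <- w$start; fe <- w$end
  } else {
    fs <- f$start; fe <- f$end
  }
  res <- switch(rule,
    full_containment = fs >= d$start & fe <= d$end,
    any_overlap = ,
    promoter_upstream_5kb = pmin(fe, d$end) - pmax(fs, d$start) > 0)
  res & same
}

# 5 kb (default) upstream-of-TSS window; the downstream end is the TSS.
promoter_window <- function(tss, strand, width = 5000) {
  plus <- strand != "-"
  start <- ifelse(plus, pmax(0, tss - width), tss)
  end <- ifelse(plus, tss, tss + width)
  # degenerate window at chromosome start still half-open and valid
  end <- pmax(end, start + 1)
  list(start = start, end = end)
}

# data.frame (chrom/start/end) -> GRanges; half-open 0-based to 1-based closed
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}
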