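#' Read and write BED intervals
#'
#' Standard BED, 0-based half-open. Columns beyond the sixth are kept as-is.
#'
#' @param path File path.
#' @return Data frame with \code{chrom}, \code{start}, \code{end} and, when
#'   present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  for (k in seq_len(min(ncol(df) - 3L, 3L))) names(df)[3L + k] <- extra[k]
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: start >= end", bad[1], path))
  df
}

#' @rdname read_bed
#' @param df Data frame with at least \code{chrom}, \code{start}, \code{end}.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # keep a contiguous BED prefix so the file stays standard
  keep <- character(0)
  for (cn in c("chrom", "start", "end", "name", "score", "strand")) {
    if (cn %in% cols) keep <- c(keep, cn) else break
  }
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write loop lists (BEDPE)
#'
#' Six coordinate columns, then optional \code{name}, \code{qvalue} and
#' per-condition contact counts. Anchor order within each loop is enforced
#' (anchor1 precedes anchor2).
#'
#' @param path File path.
#' @return Data frame with \code{chrom}, \code{start1}, \code{end1},
#'   \code{start2}, \code{end2} plus attribute columns.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 6L) stop("BEDPE file needs at least 6 columns: ", path)
  out <- data.frame(chrom = df[[1]], start1 = df[[2]], end1 = df[[3]],
                    start2 = df[[5]], end2 = df[[6]],
                    stringsAsFactors = FALSE)
  if (any(df[[1]] != df[[4]]))
    stop("inter-chromosomal loops are not supported: ", path)
  extra <- c("name", "qvalue", "count_high", "count_low")
  for (k in seq_len(min(ncol(df) - 6L, 4L))) out[[extra[k]]] <- df[[6L + k]]
  # enforce anchor ordering
  swap <- out$start2 < out$start1
  if (any(swap)) {
    s1 <- out$start1[swap]; e1 <- out$end1[swap]
    out$start1[swap] <- out$start2[swap]; out$end1[swap] <- out$end2[swap]
    out$start2[swap] <- s1; out$end2[swap] <- e1
  }
  out
}

#' @rdname read_bedpe
#' @param loops Loop data frame as returned by \code{read_bedpe}.
#' @export
write_bedpe <- function(loops, path) {
  base <- data.frame(loops$chrom, loops$start1, loops$end1,
                     loops$chrom, loops$start2, loops$end2)
  for (cn in intersect(c("name", "qvalue", "count_high", "count_low"),
                       names(loops)))
    base[[cn]] <- loops[[cn]]
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write header-keyed TSV tables (peaks, genes)
#'
#' @param path File path.
#' @return Data frame with the file's named columns.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param df Data frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sparse binned contact matrix
#'
#' Expects a bins BED (chrom/start/end, optionally a 0-based index column)
#' plus a whitespace triplet file of \code{i j count} rows over 0-based bin
#' indices with \code{i <= j} (upper triangle). The dense symmetric matrix is
#' materialized; the total count equals the triplet sum with the diagonal
#' counted once.
#'
#' @param bins_path Path to the bins BED file.
#' @param triplets_path Path to the triplet file.
#' @return A \code{contact_matrix}.
#' @seealso [contact_matrix()], [write_contact_matrix()]
#' @export
read_contact_matrix <- function(bins_path, triplets_path) {
  bed <- read_bed(bins_path)
  sizes <- tapply(bed$end, bed$chrom, max)
  sizes <- sizes[unique(bed$chrom)]  # preserve file order
  bs <- max(bed$end - bed$start)
  bins <- make_bins(stats::setNames(as.numeric(sizes), names(sizes)), bs)
  if (nrow(bins) != nrow(bed))
    stop("bins BED does not form a regular tiling: ", bins_path)
  n <- nrow(bins)
  M <- matrix(0, n, n)
  info <- file.info(triplets_path)
  if (!is.na(info$size) && info$size > 0) {
    tr <- utils::read.table(triplets_path, header = FALSE)
    if (ncol(tr) < 3L) stop("triplet file needs 3 columns: ", triplets_path)
    i <- tr[[1]]; j <- tr[[2]]; x <- tr[[3]]
    bad <- which(i < 0 | j < 0 | i >= n | j >= n)
    if (length(bad))
      stop(sprintf("triplet line %d: bin index out of range", bad[1]))
    bad <- which(x < 0)
    if (length(bad))
      stop(sprintf("triplet line %d: negative count", bad[1]))
    bad <- which(i > j)
    if (length(bad))
      stop(sprintf("triplet line %d: lower-triangular entry (i > j)", bad[1]))
    M[cbind(i + 1L, j + 1L)] <- x
    M[cbind(j + 1L, i + 1L)] <- x
  } else {
    warning("empty triplet file: ", triplets_path, " (all-zero matrix)")
  }
  contact_matrix(bins, M)
}

#' Write a contact matrix as bins BED plus upper-triangular triplets
#'
#' @param cm A \code{contact_matrix}.
#' @param bins_path,triplets_path Output paths.
#' @export
write_contact_matrix <- function(cm, bins_path, triplets_path) {
  write_bed(cm$bins, bins_path)
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                   x = cm$counts[ut])
  utils::write.table(df, triplets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(triplets_path)
}
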