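# shared simulation helpers; replicate seeds follow the pipeline convention
rep_seeds <- function(seed, condition, n_reps) {
  off <- if (condition == "high") 0L else 100L
  seed * 100L + off + seq_len(n_reps)
}

sim_condition_maps <- function(truth, depth, seed = 1L,
                               bin_size = truth$config$tad_bin_size) {
  lapply(c(high = "high", low = "low"), function(cond)
    lapply(rep_seeds(seed, cond, truth$config$hic_reps), function(s)
      simulate_contact_map(truth, cond, depth, s, bin_size = bin_size)))
}

# merged + per-replicate balanced matrices under a shared (union) mask
balanced_group_pair <- function(raw, scale_total = NULL) {
  mask <- Reduce(`|`, lapply(unlist(raw, recursive = FALSE), ice_mask))
  merged <- lapply(raw, function(cms)
    ice_normalize(merge_matrices(cms), mask = mask))
  if (!is.null(scale_total))
    merged <- lapply(merged, scale_to_total, target_total = scale_total)
  reps <- lapply(raw, function(cms)
    lapply(cms, ice_normalize, mask = mask))
  list(merged = merged, reps = reps, mask = mask)
}

# wrap a plain symmetric matrix into a contact_matrix on a toy chromosome
toy_cm <- function(M, bin_size = 1000, chrom = "cT") {
  bins <- make_bins(stats::setNames(nrow(M) * bin_size, chrom), bin_size)
  contact_matrix(bins, M)
}

# reciprocal overlap of two intervals
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  c(ov / (e1 - s1), ov / (e2 - s2))
}
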