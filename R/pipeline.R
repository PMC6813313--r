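#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis stages together with the
#' synthetic-study configuration and the run seed. All stages read their
#' thresholds from this object only.
#'
#' @param out_dir Run directory for stage artifacts.
#' @param seed Integer seed; all stage-level seeds are derived from it.
#' @param sim A \code{\link{sim_config}} for the `simulate` stage.
#' @param ... Threshold overrides (see defaults in the function body).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = "tadlink_run", seed = 1L,
                            sim = sim_config(), ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim,
    tad_bin = sim$tad_bin_size, compartment_bin = sim$comp_bin_size,
    insulation_window = sim$insulation_window,
    scale_total = 1e6,
    de_lfc = 1, de_q = 0.01,
    peak_lfc = 1, peak_q = 0.01,
    domain_diff_q = 0.05,
    boundary_lfc = 0.1, boundary_q = 0.05,
    boundary_k = 0.5,
    intratad_change = 0.3, intratad_q = 0.1,
    corr_threshold = 0.4,
    ice_tol = 1e-5, ice_max_iter = 200L, mask_low_frac = 0.02)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("de_lfc", "de_q", "peak_lfc", "peak_q", "domain_diff_q",
           "boundary_lfc", "boundary_q", "intratad_change", "intratad_q",
           "corr_threshold")
  bad <- num[vapply(num, function(k) !is.finite(cfg[[k]]) || cfg[[k]] <= 0,
                    logical(1))]
  if (length(bad))
    stop("thresholds must be positive: ", paste(bad, collapse = ", "))
  structure(cfg, class = c("pipeline_config", "list"))
}

pfile <- function(config, ...) file.path(config$out_dir, ...)

need_inputs <- function(config, files) {
  paths <- vapply(files, function(f) pfile(config, f), character(1))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input for this stage: ", paste(missing, collapse = ", "))
  invisible(paths)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

matrix_paths <- function(config, grid, cond) {
  reps <- config$sim$hic_reps
  sprintf("matrix_%s_%s_rep%d.txt", grid, cond, seq_len(reps))
}

load_raw <- function(config, grid, cond) {
  bins <- sprintf("bins_%s.bed", grid)
  files <- matrix_paths(config, grid, cond)
  need_inputs(config, c(bins, files))
  lapply(files, function(f)
    read_contact_matrix(pfile(config, bins), pfile(config, f)))
}

# union coverage mask over all replicates of both conditions: comparisons
# between samples must share a bin mask so bias estimation is comparable
grid_mask <- function(config, raw_by_cond) {
  masks <- lapply(unlist(raw_by_cond, recursive = FALSE), ice_mask,
                  mask_low_frac = config$mask_low_frac)
  Reduce(`|`, masks)
}

# ICE at native totals; insulation scoring depends on a count-scale
# pseudocount, so only cross-sample intensity comparisons get rescaled
balance <- function(config, cm, mask = NULL) {
  ice_normalize(cm, tol = config$ice_tol,
                max_iter = config$ice_max_iter,
                mask_low_frac = config$mask_low_frac, mask = mask)
}

# balanced merged + per-replicate matrices for both conditions, shared mask
grid_matrices <- function(config, grid) {
  raw <- lapply(c(high = "high", low = "low"), function(cond)
    load_raw(config, grid, cond))
  mask <- grid_mask(config, raw)
  merged <- lapply(raw, function(cms)
    balance(config, merge_matrices(cms), mask = mask))
  reps <- lapply(raw, function(cms)
    lapply(cms, balance, config = config, mask = mask))
  list(merged = merged, reps = reps, mask = mask)
}

stage_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config$sim, seed = config$seed)
  feats <- simulate_feature_tables(truth, seed = config$seed + 1L)
  write_bed(truth$bins_tad, pfile(config, "bins_tad.bed"))
  write_bed(truth$bins_comp, pfile(config, "bins_comp.bed"))
  for (cond in c("high", "low")) {
    off <- if (cond == "high") 100L else 200L
    for (r in seq_len(config$sim$hic_reps)) {
      for (grid in c("tad", "comp")) {
        bsz <- if (grid == "tad") config$tad_bin else config$compartment_bin
        cm <- simulate_contact_map(truth, cond, depth = config$sim$hic_depth,
                                   replicate_seed = config$seed + off + r,
                                   bin_size = bsz)
        write_contact_matrix(cm, pfile(config, sprintf("bins_%s.bed", grid)),
                             pfile(config, sprintf("matrix_%s_%s_rep%d.txt",
                                                   grid, cond, r)))
      }
    }
  }
  for (nm in names(feats$peaks))
    write_tsv_stable(feats$peaks[[nm]],
                     pfile(config, sprintf("peaks_%s.tsv", nm)))
  write_tsv_stable(feats$genes, pfile(config, "genes.tsv"))
  write_bedpe(feats$loops_high, pfile(config, "loops_high.bedpe"))
  write_bedpe(feats$loops_low, pfile(config, "loops_low.bedpe"))
  for (nm in names(feats$marks))
    write_tsv_stable(cbind(feats$mark_bins[, c("chrom", "start", "end")],
                           as.data.frame(feats$marks[[nm]])),
                     pfile(config, sprintf("marks_%s.tsv", nm)))
  truth_small <- truth[c("tads", "boundaries", "compartments", "glm_beta")]
  truth_small$genes <- truth$genes[, c("gene_id", "de_true", "p_de",
                                       "k27ac.tad", "ctcf.tad",
                                       "k27ac.loop", "ctcf.loop")]
  jsonlite::write_json(truth_small, pfile(config, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

stage_normalize <- function(config) {
  for (grid in c("tad", "comp")) {
    bins <- sprintf("bins_%s.bed", grid)
    raw <- lapply(c(high = "high", low = "low"), function(cond)
      load_raw(config, grid, cond))
    mask <- grid_mask(config, raw)
    for (cond in c("high", "low")) {
      files <- matrix_paths(config, grid, cond)
      for (k in seq_along(files)) {
        cm <- balance(config, raw[[cond]][[k]], mask = mask)
        cm$counts <- round(cm$counts, 4)  # byte-stable artifacts
        write_contact_matrix(cm, pfile(config, bins),
                             pfile(config, sub("^matrix", "balanced",
                                               files[k])))
        bias <- data.frame(index = cm$bins$index, bias = fmt_num(cm$bias),
                           masked = cm$mask)
        utils::write.table(bias,
                           pfile(config, sub("^matrix", "bias",
                                             sub(".txt$", ".tsv", files[k]))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(NULL)
}

stage_boundaries <- function(config) {
  w <- max(1L, floor(config$insulation_window / config$tad_bin))
  gm <- grid_matrices(config, "tad")
  merged <- gm$merged
  tracks_merged <- lapply(merged, ratio_insulation, window_bins = w)
  calls <- lapply(tracks_merged, call_tads_and_boundaries,
                  bins = merged$low$bins, k = config$boundary_k)
  for (cond in c("high", "low")) {
    write_bed(calls[[cond]]$tads, pfile(config, sprintf("tads_%s.bed", cond)))
    write_tsv_stable(calls[[cond]]$boundaries,
                     pfile(config, sprintf("boundaries_%s.tsv", cond)))
  }
  rep_tracks <- lapply(gm$reps, function(cms)
    lapply(cms, ratio_insulation, window_bins = w))
  diffb <- differential_boundaries(rep_tracks$high, rep_tracks$low,
                                   calls$low$boundaries, merged$low$bins,
                                   lfc_threshold = config$boundary_lfc,
                                   q_threshold = config$boundary_q)
  need_inputs(config, c("peaks_ctcf.tsv", "peaks_rad21.tsv"))
  ctcf <- read_tsv_table(pfile(config, "peaks_ctcf.tsv"))
  rad21 <- read_tsv_table(pfile(config, "peaks_rad21.tsv"))
  occ_c <- boundary_occupancy(ctcf, calls$low$boundaries, config$tad_bin)
  occ_r <- boundary_occupancy(rad21, calls$low$boundaries, config$tad_bin)
  diffb$ctcf_log2fc <- occ_c$occ_log2fc
  diffb$ctcf_pvalue <- occ_c$occ_pvalue
  diffb$rad21_log2fc <- occ_r$occ_log2fc
  diffb$rad21_pvalue <- occ_r$occ_pvalue
  write_tsv_stable(diffb, pfile(config, "boundaries_differential.tsv"))
  tr <- data.frame(index = seq_along(tracks_merged$high) - 1L,
                   ratio_high = fmt_num(as.numeric(tracks_merged$high)),
                   ratio_low = fmt_num(as.numeric(tracks_merged$low)))
  utils::write.table(tr, pfile(config, "insulation_tracks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(diffb)
}

stage_tads <- function(config) {
  need_inputs(config, c("tads_high.bed", "tads_low.bed"))
  tads_h <- read_bed(pfile(config, "tads_high.bed"))
  tads_l <- read_bed(pfile(config, "tads_low.bed"))
  common <- find_common_tads(tads_l, tads_h, config$tad_bin)
  gm <- grid_matrices(config, "tad")
  res <- intra_tad_change(scale_to_total(gm$merged$low, config$scale_total),
                          scale_to_total(gm$merged$high, config$scale_total),
                          common)
  res <- classify_intra_tad(res, fdr = config$intratad_q,
                            min_abs_change = config$intratad_change)
  write_tsv_stable(res, pfile(config, "intratad.tsv"))
  invisible(res)
}

stage_compartments <- function(config) {
  need_inputs(config, "peaks_h3k27ac.tsv")
  k27 <- read_tsv_table(pfile(config, "peaks_h3k27ac.tsv"))
  merged <- grid_matrices(config, "comp")$merged
  pc1 <- lapply(merged, compute_pc1, active_peaks = k27)
  strengths <- list()
  for (cond in c("high", "low")) {
    tr <- pc1[[cond]]
    bg <- data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                     name = ".", score = fmt_num(tr$pc1))
    write_bed(bg, pfile(config, sprintf("pc1_%s.bedgraph", cond)))
    sad <- saddle_matrix(tr, merged[[cond]])
    utils::write.table(round(sad$saddle, 6),
                       pfile(config, sprintf("saddle_%s.tsv", cond)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    strengths[[cond]] <- compartment_strength(sad)
  }
  jsonlite::write_json(strengths, pfile(config, "compartment_strength.json"),
                       auto_unbox = TRUE, digits = NA)
  sw <- detect_switching(pc1$high, pc1$low, merged$high, merged$low,
                         corr_threshold = config$corr_threshold)
  write_tsv_stable(sw, pfile(config, "switch_regions.tsv"))
  invisible(sw)
}

stage_integrate <- function(config) {
  need_inputs(config, c("intratad.tsv", "switch_regions.tsv", "genes.tsv",
                        "peaks_ctcf.tsv", "peaks_h3k27ac.tsv",
                        "loops_high.bedpe", "loops_low.bedpe",
                        "pc1_high.bedgraph", "pc1_low.bedgraph"))
  common <- read_tsv_table(pfile(config, "intratad.tsv"))
  sw <- read_tsv_table(pfile(config, "switch_regions.tsv"))
  genes <- read_tsv_table(pfile(config, "genes.tsv"))
  ctcf <- read_tsv_table(pfile(config, "peaks_ctcf.tsv"))
  k27 <- read_tsv_table(pfile(config, "peaks_h3k27ac.tsv"))
  nd <- nrow(common)
  mean_of <- function(features, kind, gene = FALSE, domains = common)
    domain_mean_lfc(assign_features_to_domains(features, domains, kind,
                                               feature_is_gene = gene),
                    features, nrow(domains), mode = "all")
  common$mean_lfc_ctcf <- mean_of(ctcf, "common_tad")
  common$mean_lfc_k27ac <- mean_of(k27, "common_tad")
  common$mean_lfc_rna <- mean_of(genes, "common_tad")
  read_bg <- function(cond) {
    bg <- read_bed(pfile(config, sprintf("pc1_%s.bedgraph", cond)))
    pc1 <- suppressWarnings(as.numeric(bg$score))
    data.frame(chrom = bg$chrom, start = bg$start, end = bg$end, pc1 = pc1,
               label = ifelse(is.na(pc1), "masked",
                              ifelse(pc1 > 0, "A", "B")))
  }
  common <- tad_pc1_diff(read_bg("high"), read_bg("low"), common, sw)
  cs <- correlation_summary(common,
                            features = c("mean_lfc_ctcf", "mean_lfc_k27ac",
                                         "mean_lfc_rna", "change",
                                         "pc1_diff"))
  write_tsv_stable(cs$table, pfile(config, "domain_summary.tsv"))
  if (!is.null(cs$correlations))
    write_tsv_stable(as.data.frame(round(cs$correlations, 6)),
                     pfile(config, "domain_correlations.tsv"))
  loops_h <- read_bedpe(pfile(config, "loops_high.bedpe"))
  loops_l <- read_bedpe(pfile(config, "loops_low.bedpe"))
  cl <- common_loops(loops_h, loops_l)
  if (nrow(cl)) {
    cl$mean_lfc_ctcf <- mean_of(ctcf, "loop", domains = cl)
    cl$mean_lfc_k27ac <- mean_of(k27, "loop", domains = cl)
    cl$mean_lfc_rna <- mean_of(genes, "loop", gene = TRUE, domains = cl)
  }
  write_tsv_stable(cl, pfile(config, "loop_summary.tsv"))
  # broad marks on switch regions
  for (mark in c("h3k36me2", "h3k27me3")) {
    f <- sprintf("marks_%s.tsv", mark)
    if (!file.exists(pfile(config, f))) next
    mk <- read_tsv_table(pfile(config, f))
    hi <- as.matrix(mk[, grep("^high_", names(mk)), drop = FALSE])
    lo <- as.matrix(mk[, grep("^low_", names(mk)), drop = FALSE])
    hits <- overlap_hits(mk[, c("chrom", "start", "end")], sw)
    ch <- rowsum(hi[hits$feature, , drop = FALSE], hits$domain)
    cl2 <- rowsum(lo[hits$feature, , drop = FALSE], hits$domain)
    lfc <- binned_mark_lfc(ch, cl2)
    out <- sw[as.integer(rownames(ch)), , drop = FALSE]
    out[[paste0(mark, "_lfc")]] <- lfc
    write_tsv_stable(out, pfile(config, sprintf("switch_%s.tsv", mark)))
  }
  invisible(common)
}

stage_glm <- function(config) {
  need_inputs(config, c("genes.tsv", "peaks_ctcf.tsv", "peaks_h3k27ac.tsv",
                        "tads_high.bed", "tads_low.bed",
                        "loops_high.bedpe", "loops_low.bedpe"))
  genes <- read_tsv_table(pfile(config, "genes.tsv"))
  genes$de_flag <- abs(genes$log2fc) > config$de_lfc &
    genes$qvalue < config$de_q
  ctcf <- read_tsv_table(pfile(config, "peaks_ctcf.tsv"))
  k27 <- read_tsv_table(pfile(config, "peaks_h3k27ac.tsv"))
  tads <- rbind(read_bed(pfile(config, "tads_high.bed"))[, 1:3],
                read_bed(pfile(config, "tads_low.bed"))[, 1:3])
  loops_h <- read_bedpe(pfile(config, "loops_high.bedpe"))
  loops_l <- read_bedpe(pfile(config, "loops_low.bedpe"))
  loops <- rbind(loops_h[, c("chrom", "start1", "end1", "start2", "end2")],
                 loops_l[, c("chrom", "start1", "end1", "start2", "end2")])
  design <- build_design(genes, ctcf, k27, tads, loops,
                         peak_lfc = config$peak_lfc, peak_q = config$peak_q,
                         de_lfc = config$de_lfc, de_q = config$de_q)
  write_tsv_stable(design, pfile(config, "design.tsv"))
  fit <- fit_logistic(design)
  write_tsv_stable(fit$coefficients, pfile(config, "glm_coefficients.tsv"))
  dp <- function(pk) pk[abs(pk$log2fc) > config$peak_lfc &
                          pk$qvalue < config$peak_q, , drop = FALSE]
  summ <- summarize_linkage(design, genes, tads, loops, dp(ctcf), dp(k27))
  jsonlite::write_json(summ, pfile(config, "linkage_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

write_manifest <- function(config) {
  cfg_path <- pfile(config, "config.yaml")
  flat <- unclass(config)
  flat$out_dir <- NULL  # location is not an analysis parameter
  flat$sim <- unclass(flat$sim)
  yaml::write_yaml(flat, cfg_path)
  manifest <- list(package = "tadlink",
                   version = as.character(utils::packageVersion("tadlink")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, pfile(config, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages write plain-text artifacts into \code{config$out_dir}; reruns with
#' the same configuration and seed reproduce them byte for byte. Each stage
#' checks that its inputs exist before writing anything.
#'
#' @param stage One of \code{"simulate"}, \code{"normalize"},
#'   \code{"boundaries"}, \code{"tads"}, \code{"compartments"},
#'   \code{"integrate"}, \code{"glm"}, \code{"all"}.
#' @param config A [pipeline_config()].
#' @return Invisibly, the last stage's main result.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "normalize",
                                   "boundaries", "tads", "compartments",
                                   "integrate", "glm"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  stages <- if (stage == "all")
    c("simulate", "normalize", "boundaries", "tads", "compartments",
      "integrate", "glm")
  else stage
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- NULL
  for (s in stages) {
    message("[tadlink] stage: ", s)
    res <- switch(s,
      simulate = stage_simulate(config),
      normalize = stage_normalize(config),
      boundaries = stage_boundaries(config),
      tads = stage_tads(config),
      compartments = stage_compartments(config),
      integrate = stage_integrate(config),
      glm = stage_glm(config))
  }
  write_manifest(config)
  invisible(res)
}
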