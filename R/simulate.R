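#' Default configuration for the synthetic two-condition study
#'
#' Returns the generator configuration: a single synthetic chromosome carrying
#' planted TADs, insulating boundaries, checkerboard A/B compartments with
#' condition-specific flips, ChIP peak tables with differential subsets, a
#' gene table whose differential-expression status follows a logistic model on
#' domain covariates, loop lists anchored at CTCF sites, and binned coverage
#' for broad marks. Any entry can be overridden via \code{...}.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_name = "chrS",
    chrom_length = 2e7,
    tad_bin_size = 4e4,
    comp_bin_size = 5e4,
    insulation_window = 5e5,
    # TAD / boundary structure
    n_tads = 25L,
    min_tad_bins = 10L,
    tad_enrichment = 2.0,
    n_gain_tads = 3L,
    n_loss_tads = 0L,
    gain_factor = 1.5,
    boundary_attenuation = 0.5,
    n_diff_boundaries = 3L,
    boundary_strength_fc = 2.0,
    boundary_window_bins = 12L,
    boundary_zone_bins = 3L,
    # per-bin visibility (mappability/GC) biases removed by ICE
    visibility_sd = 0.25,
    frac_invisible = 0.01,
    # compartments
    comp_block_size = 1e6,
    gamma = 0.4,
    n_flips = 1L,
    flip_direction = "BA",
    # peaks
    n_ctcf = 150L, n_k27ac = 150L, n_rad21 = 120L,
    n_diff_ctcf = 20L, n_diff_k27ac = 20L,
    n_chromatin_tads = 8L,
    peak_diff_lfc = 2.0,
    chip_reps = 3L,
    chip_cv = 0.1,
    # genes
    n_genes = 400L,
    glm_beta = c(intercept = -2, k27ac.tad = 1.0, ctcf.tad = 0.8,
                 k27ac.loop = 0.6, ctcf.loop = 0.9),
    de_lfc = 1, de_q = 0.01,
    rna_reps = 3L,
    nb_dispersion = 0.1,
    # loops
    loop_bin_size = 1e4,
    n_common_loops = 50L,
    n_unique_loops = 5L,
    loop_min_span = 2e4,
    loop_max_span = 3e6,
    # broad marks
    mark_reps = 2L,
    # Hi-C sampling
    hic_reps = 2L,
    hic_depth = 2e6
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("sim_config", "list"))
}

#' Generate the ground truth of a synthetic two-condition study
#'
#' Deterministic given \code{(config, seed)}. Every planted effect (enriched
#' TADs, strengthened boundaries, compartment flips, differential peaks, DE
#' genes) is recorded so downstream recovery can be scored exactly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed.
#' @return A list of class \code{sim_truth} with bin tables, \code{tads},
#'   \code{boundaries}, \code{compartments}, \code{peaks}, \code{genes},
#'   \code{loops}, and \code{glm_beta}.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1L) {
  set.seed(as.integer(seed))
  cfg <- config
  chrom <- cfg$chrom_name
  L <- cfg$chrom_length
  bs <- cfg$tad_bin_size
  n_bins <- floor(L / bs)
  sizes <- stats::setNames(L, chrom)
  bins_tad <- make_bins(sizes, bs)
  bins_comp <- make_bins(sizes, cfg$comp_bin_size)

  ## --- TAD partition ---------------------------------------------------
  if (cfg$n_tads > 0L) {
    min_b <- cfg$min_tad_bins
    extra <- n_bins - cfg$n_tads * min_b
    if (extra < 0)
      stop("infeasible placement: too many TADs for the chromosome length")
    add <- as.vector(stats::rmultinom(1, extra, rep(1, cfg$n_tads)))
    widths <- min_b + add
    ends <- cumsum(widths)
    starts <- c(0L, ends[-cfg$n_tads])
    tads <- data.frame(chrom = chrom, start = starts * bs, end = ends * bs,
                       tad_id = sprintf("tad%03d", seq_len(cfg$n_tads)),
                       stringsAsFactors = FALSE)
    tads$enrich_low <- cfg$tad_enrichment
    tads$enrich_high <- cfg$tad_enrichment
    tads$class <- "Stable"
    nd <- cfg$n_gain_tads + cfg$n_loss_tads
    if (nd > cfg$n_tads) stop("infeasible placement: too many differential TADs")
    dyn <- sample(cfg$n_tads, nd)
    gains <- utils::head(dyn, cfg$n_gain_tads)
    losses <- utils::tail(dyn, cfg$n_loss_tads)
    tads$enrich_high[gains] <- tads$enrich_high[gains] * cfg$gain_factor
    tads$class[gains] <- "Gain"
    tads$enrich_high[losses] <- tads$enrich_high[losses] / cfg$gain_factor
    tads$class[losses] <- "Loss"
  } else {
    tads <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), tad_id = character(0),
                       enrich_low = numeric(0), enrich_high = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
  }

  ## --- boundaries (internal TAD junctions) ------------------------------
  if (nrow(tads) > 1L) {
    junc <- tads$start[-1L]
    nb <- length(junc)
    zone <- cfg$boundary_zone_bins * bs
    boundaries <- data.frame(
      chrom = chrom,
      start = junc - zone, end = junc + zone,  # planted insulation zone
      boundary_id = sprintf("bnd%03d", seq_len(nb)),
      center = junc,
      atten_low = cfg$boundary_attenuation,
      atten_high = cfg$boundary_attenuation,
      differential = FALSE, stringsAsFactors = FALSE)
    if (cfg$n_diff_boundaries > nb)
      stop("infeasible placement: too many differential boundaries")
    db <- sample(nb, cfg$n_diff_boundaries)
    boundaries$atten_high[db] <-
      boundaries$atten_high[db] / cfg$boundary_strength_fc
    boundaries$differential[db] <- TRUE
  } else {
    boundaries <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), boundary_id = character(0),
                             center = numeric(0), atten_low = numeric(0),
                             atten_high = numeric(0),
                             differential = logical(0))
  }

  ## --- compartments: alternating blocks with planted flips --------------
  ## Block sizes are drawn around comp_block_size (0.6-1.4x, on the
  ## compartment grid) so that label agreement does not correlate with
  ## genomic distance; a regular lattice would let the distance-decay
  ## expectation absorb most of the compartment contrast.
  if (cfg$gamma > 0) {
    cb <- cfg$comp_bin_size
    mean_bins <- max(2L, round(cfg$comp_block_size / cb))
    lo_b <- max(1L, round(0.6 * mean_bins))
    hi_b <- max(lo_b + 1L, round(1.4 * mean_bins))
    n_max <- ceiling(L / (lo_b * cb)) + 2L
    sizes <- sample(lo_b:hi_b, n_max, replace = TRUE)
    lab_all <- rep(c("A", "B"), length.out = n_max)
    from <- if (cfg$flip_direction == "BA") "B" else "A"
    to <- if (from == "B") "A" else "B"
    fl <- integer(0)
    if (cfg$n_flips > 0L) {
      n_used <- which(cumsum(sizes * cb) >= L)[1]
      cand <- which(lab_all == from)
      cand <- cand[cand > 1 & cand < n_used]
      if (cfg$n_flips > length(cand))
        stop("infeasible placement: too many compartment flips")
      fl <- sample(cand, cfg$n_flips)
      sizes[fl] <- mean_bins  # planted flips span exactly one block size
    }
    bend <- pmin(cumsum(sizes * cb), L)
    keep <- which(c(bend[1], diff(bend)) > 0)
    bstart <- c(0, bend[-length(bend)])[keep]
    bend <- bend[keep]
    comp <- data.frame(chrom = chrom, start = bstart, end = bend,
                       label_low = lab_all[keep], label_high = lab_all[keep],
                       flip = "Stable", stringsAsFactors = FALSE)
    if (length(fl)) {
      fidx <- match(fl, keep)
      fidx <- fidx[!is.na(fidx)]
      comp$label_high[fidx] <- to
      comp$flip[fidx] <- cfg$flip_direction
    }
  } else {
    comp <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), label_low = character(0),
                       label_high = character(0), flip = character(0))
  }

  ## --- per-bin visibility biases (shared by both conditions) ------------
  n_tb <- nrow(bins_tad)
  visibility <- stats::rlnorm(n_tb, meanlog = 0, sdlog = cfg$visibility_sd)
  n_inv <- round(cfg$frac_invisible * n_tb)
  if (n_inv > 0) visibility[sample(n_tb, n_inv)] <- 0.02

  ## --- chromatin-altered TADs driving peaks and genes -------------------
  n_ct <- min(cfg$n_chromatin_tads, nrow(tads))
  chrom_tads <- if (n_ct > 0L) sort(sample(nrow(tads), n_ct)) else integer(0)
  tad_dir <- stats::setNames(rep(0, nrow(tads)), tads$tad_id)
  tad_dir[chrom_tads] <- sample(c(-1, 1), n_ct, replace = TRUE)

  place_diff <- function(n_diff) {
    # 70% of differential peaks inside chromatin-altered TADs
    n_in <- if (n_ct > 0L) round(0.7 * n_diff) else 0L
    pos <- numeric(0); dir <- numeric(0)
    if (n_in > 0L) {
      tsel <- sample(chrom_tads, n_in, replace = TRUE)
      pos <- stats::runif(n_in, tads$start[tsel] + 1000,
                          tads$end[tsel] - 1000)
      dir <- tad_dir[tsel]
    }
    n_out <- n_diff - n_in
    if (n_out > 0L) {
      pos <- c(pos, stats::runif(n_out, 1000, L - 1000))
      dir <- c(dir, sample(c(-1, 1), n_out, replace = TRUE))
    }
    list(pos = pos, dir = dir)
  }

  # positions biased into stable A compartments (active chromatin)
  sample_active_pos <- function(n) {
    blocks <- comp[comp$label_low == "A" & comp$label_high == "A", ,
                   drop = FALSE]
    if (nrow(blocks) == 0L) return(stats::runif(n, 1000, L - 1000))
    w <- blocks$end - blocks$start
    b <- sample(nrow(blocks), n, replace = TRUE, prob = w)
    stats::runif(n, blocks$start[b] + 100, blocks$end[b] - 100)
  }

  make_peaks <- function(n, n_diff, prefix, at_boundaries = FALSE,
                         active_frac = 0) {
    pos <- stats::runif(n, 1000, L - 1000)
    if (active_frac > 0) {
      na <- round(active_frac * n)
      if (na > 0) pos[seq_len(na)] <- sample_active_pos(na)
      pos <- pos[sample.int(n)]
    }
    dirs <- rep(0, n)
    is_diff <- rep(FALSE, n)
    k <- 0L
    if (at_boundaries && nrow(boundaries) > 0L) {
      k <- min(nrow(boundaries), n)
      pos[seq_len(k)] <- boundaries$center[seq_len(k)]
      # boundary CTCF/Rad21 gains binding where insulation strengthens
      bd <- which(boundaries$differential[seq_len(k)])
      dirs[bd] <- 1
      is_diff[bd] <- TRUE
    }
    n_extra <- max(0L, n_diff - sum(is_diff))
    if (n_extra > 0L) {
      pd <- place_diff(n_extra)
      free <- which(!is_diff & seq_len(n) > k)
      sel <- utils::head(free, n_extra)
      pos[sel] <- pd$pos[seq_along(sel)]
      dirs[sel] <- pd$dir[seq_along(sel)]
      is_diff[sel] <- TRUE
    }
    w <- stats::runif(n, 200, 600)
    mean_low <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.6)
    lfc <- ifelse(is_diff, dirs * cfg$peak_diff_lfc, 0)
    # boundary-linked differential peaks move one log2 unit with insulation
    if (at_boundaries && k > 0L) lfc[seq_len(k)] <- dirs[seq_len(k)]
    data.frame(chrom = chrom,
               start = pmax(0, round(pos - w / 2)),
               end = pmin(L, round(pos + w / 2)),
               feature_id = sprintf("%s%04d", prefix, seq_len(n)),
               mean_low = mean_low,
               mean_high = mean_low * 2^lfc,
               true_log2fc = lfc,
               differential = is_diff,
               stringsAsFactors = FALSE)
  }

  ctcf <- make_peaks(cfg$n_ctcf, cfg$n_diff_ctcf, "ctcf", at_boundaries = TRUE)
  k27ac <- make_peaks(cfg$n_k27ac, cfg$n_diff_k27ac, "k27ac",
                      active_frac = 0.8)
  rad21 <- make_peaks(cfg$n_rad21, max(0L, cfg$n_diff_ctcf %/% 2L), "rad21",
                      at_boundaries = TRUE)

  ## --- loops anchored at CTCF sites -------------------------------------
  make_loop_set <- function(n) {
    out <- data.frame()
    guard <- 0L
    mid <- (ctcf$start + ctcf$end) / 2
    while (nrow(out) < n && guard < 50L * n) {
      guard <- guard + 1L
      # spans lognormal around ~200 kb, the scale of CTCF loops
      target <- stats::rlnorm(1, meanlog = log(2e5), sdlog = 0.6)
      a1 <- sample(length(mid), 1L)
      a2 <- which.min(abs(mid - (mid[a1] + target)))
      if (a1 == a2) next
      p <- sort(mid[c(a1, a2)])
      span <- p[2] - p[1]
      if (span < cfg$loop_min_span || span > cfg$loop_max_span) next
      hw <- cfg$loop_bin_size / 2
      row <- data.frame(chrom = chrom,
                        start1 = max(0, round(p[1] - hw)),
                        end1 = round(p[1] + hw),
                        start2 = round(p[2] - hw),
                        end2 = min(L, round(p[2] + hw)))
      out <- rbind(out, row)
      out <- out[!duplicated(out[, c("start1", "start2")]), ]
    }
    out
  }
  common <- make_loop_set(cfg$n_common_loops)
  if (nrow(common) > 0)
    common$name <- sprintf("loop%04d", seq_len(nrow(common)))
  uniq_h <- make_loop_set(cfg$n_unique_loops)
  uniq_l <- make_loop_set(cfg$n_unique_loops)
  if (nrow(uniq_h) > 0) uniq_h$name <- sprintf("hloop%03d", seq_len(nrow(uniq_h)))
  if (nrow(uniq_l) > 0) uniq_l$name <- sprintf("lloop%03d", seq_len(nrow(uniq_l)))

  ## --- genes with logistic DE model on domain covariates ----------------
  ng <- cfg$n_genes
  glen <- stats::runif(ng, 2e3, 5e4)
  gstart <- stats::runif(ng, 0, L - glen)
  genes <- data.frame(chrom = chrom, start = round(gstart),
                      end = round(gstart + glen),
                      gene_id = sprintf("gene%05d", seq_len(ng)),
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  diff_ctcf <- ctcf[ctcf$differential, ]
  diff_k27 <- k27ac[k27ac$differential, ]
  X <- design_covariates(genes, diff_ctcf, diff_k27, tads, common)
  eta <- cfg$glm_beta[1] +
    as.matrix(X[, c("k27ac.tad", "ctcf.tad", "k27ac.loop", "ctcf.loop")]) %*%
    cfg$glm_beta[-1]
  genes$p_de <- as.vector(stats::plogis(eta))
  genes$de_true <- stats::rbinom(ng, 1, genes$p_de) == 1
  genes <- cbind(genes, X[, c("k27ac.tad", "ctcf.tad",
                              "k27ac.loop", "ctcf.loop")])

  # direction: genes in a chromatin-altered TAD follow that TAD's direction
  gdir <- sample(c(-1, 1), ng, replace = TRUE)
  if (length(chrom_tads)) {
    for (ti in chrom_tads) {
      inside <- genes$start >= tads$start[ti] & genes$end <= tads$end[ti]
      gdir[inside] <- tad_dir[ti]
    }
  }
  # reported log2fc/qvalue consistent with the drawn DE status
  lfc <- numeric(ng); qv <- numeric(ng)
  de <- genes$de_true
  lfc[de] <- gdir[de] * (cfg$de_lfc + 0.2 + stats::rexp(sum(de), 1))
  qv[de] <- stats::runif(sum(de), 0, cfg$de_q * 0.9)
  big <- !de & stats::runif(ng) < 0.1
  lfc[!de] <- gdir[!de] * stats::runif(sum(!de), 0, 0.95 * cfg$de_lfc)
  lfc[big] <- gdir[big] * stats::runif(sum(big), cfg$de_lfc, 2 * cfg$de_lfc)
  qv[!de & !big] <- stats::runif(sum(!de & !big), 0, 1)
  qv[big] <- stats::runif(sum(big), 2 * cfg$de_q, 1)
  genes$true_log2fc <- lfc
  genes$true_qvalue <- qv
  genes$nb_mu <- stats::rlnorm(ng, meanlog = log(200), sdlog = 1)

  structure(list(config = cfg, seed = as.integer(seed),
                 bins_tad = bins_tad, bins_comp = bins_comp,
                 tads = tads, boundaries = boundaries,
                 compartments = comp,
                 peaks = list(ctcf = ctcf, h3k27ac = k27ac, rad21 = rad21),
                 genes = genes,
                 loops = list(common = common, unique_high = uniq_h,
                              unique_low = uniq_l),
                 visibility = visibility,
                 glm_beta = cfg$glm_beta),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_truth: %s (%.1f Mb), %d TADs (%d Gain/%d Loss), %d boundaries ",
    "(%d differential), %d compartment flips, %d genes (%d DE)\n"),
    x$config$chrom_name, x$config$chrom_length / 1e6,
    nrow(x$tads), sum(x$tads$class == "Gain"), sum(x$tads$class == "Loss"),
    nrow(x$boundaries), sum(x$boundaries$differential),
    sum(x$compartments$flip != "Stable"), nrow(x$genes), sum(x$genes$de_true)))
  invisible(x)
}

# per-bin compartment label for a condition ("" where undefined)
comp_label_at <- function(truth, mids, condition) {
  comp <- truth$compartments
  lab <- rep("", length(mids))
  if (nrow(comp) == 0L) return(lab)
  col <- if (condition == "high") "label_high" else "label_low"
  k <- findInterval(mids, comp$start)
  ok <- k >= 1 & mids < comp$end[pmax(k, 1)]
  lab[ok] <- comp[[col]][k[ok]]
  lab
}

# expected (unscaled) contact structure for one condition and bin grid
expected_structure <- function(truth, condition, bin_size) {
  cfg <- truth$config
  bins <- if (bin_size == cfg$tad_bin_size) truth$bins_tad
          else if (bin_size == cfg$comp_bin_size) truth$bins_comp
          else make_bins(stats::setNames(cfg$chrom_length, cfg$chrom_name),
                         bin_size)
  n <- nrow(bins)
  mids <- (bins$start + bins$end) / 2
  E <- 1 / (abs(outer(seq_len(n), seq_len(n), "-")) + 1)
  if (nrow(truth$tads) > 0L) {
    ecol <- if (condition == "high") "enrich_high" else "enrich_low"
    for (t in seq_len(nrow(truth$tads))) {
      idx <- which(mids >= truth$tads$start[t] & mids < truth$tads$end[t])
      if (length(idx)) E[idx, idx] <- E[idx, idx] * truth$tads[[ecol]][t]
    }
  }
  if (nrow(truth$boundaries) > 0L) {
    ## Boundaries are extended insulator zones, not point insulators: every
    ## contact whose span crosses any part of the zone is attenuated by the
    ## condition's full attenuation factor. Uniform depletion across the
    ## zone yields a plateau of comparably elevated ratio scores over
    ## several bins, the multi-bin boundary regions that Crane-type callers
    ## report (median 7 bins in ChIP-grade Hi-C); a "2x-strengthened"
    ## boundary halves its crossing contacts.
    acol <- if (condition == "high") "atten_high" else "atten_low"
    w_bp <- cfg$boundary_window_bins * cfg$tad_bin_size
    z_bp <- cfg$boundary_zone_bins * cfg$tad_bin_size
    for (b in seq_len(nrow(truth$boundaries))) {
      c0 <- truth$boundaries$center[b]
      nb_idx <- which(abs(mids - c0) <= w_bp + z_bp)
      if (length(nb_idx) < 2L) next
      a <- truth$boundaries[[acol]][b]
      m <- mids[nb_idx]
      # a pair crosses the zone when its span intersects it; contacts lying
      # entirely within the zone are local and stay intact
      lo <- outer(m, m, pmin); hi <- outer(m, m, pmax)
      crosses <- lo < c0 + z_bp & hi > c0 - z_bp & lo != hi &
        !(lo >= c0 - z_bp & hi <= c0 + z_bp)
      E[nb_idx, nb_idx][crosses] <- E[nb_idx, nb_idx][crosses] * a
    }
  }
  # visibility biases act multiplicatively on both fragment ends
  v <- truth$visibility[
    pmin(length(truth$visibility),
         floor(mids / truth$config$tad_bin_size) + 1L)]
  E <- E * outer(v, v)
  if (nrow(truth$compartments) > 0L && cfg$gamma > 0) {
    lab <- comp_label_at(truth, mids, condition)
    ok <- lab != ""
    same <- outer(lab, lab, "==") & outer(ok, ok, "&")
    fac <- matrix(1, n, n)
    fac[same] <- 1 + cfg$gamma
    fac[!same & outer(ok, ok, "&")] <- 1 - cfg$gamma
    E <- E * fac
  }
  list(bins = bins, E = E)
}

#' Simulate one replicate contact map
#'
#' Expected counts follow a power-law distance decay \code{(s+1)^-1}
#' multiplied by planted TAD enrichment, boundary attenuation (cross-boundary
#' pairs within the insulation window), and checkerboard compartment factors
#' \code{(1+gamma)} (same label) / \code{(1-gamma)} (cross label), scaled to
#' the requested sequencing depth. Observed counts are Poisson.
#'
#' @param truth A \code{sim_truth}.
#' @param condition \code{"high"} or \code{"low"}.
#' @param depth Expected total read-pair count (> 0).
#' @param replicate_seed Integer seed for this replicate.
#' @param bin_size Grid resolution in bp (defaults to the TAD grid).
#' @return A raw \code{contact_matrix}.
#' @export
simulate_contact_map <- function(truth, condition = c("high", "low"),
                                 depth = truth$config$hic_depth,
                                 replicate_seed = 1L,
                                 bin_size = truth$config$tad_bin_size) {
  condition <- match.arg(condition)
  if (!is.finite(depth) || depth <= 0) stop("depth must be positive")
  es <- expected_structure(truth, condition, bin_size)
  E <- es$E
  n <- nrow(E)
  ut <- upper.tri(E, diag = TRUE)
  E <- E * (depth / sum(E[ut]))
  set.seed(as.integer(replicate_seed))
  M <- matrix(0, n, n)
  M[ut] <- stats::rpois(sum(ut), E[ut])
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  contact_matrix(es$bins, M)
}

#' Simulate observed feature tables from the ground truth
#'
#' Peak tables get per-replicate log-normal intensities around the condition
#' mean; their reported \code{log2fc}/\code{qvalue} are computed from the
#' simulated replicates by a two-sample t-test on log2 intensities with BH
#' correction (a stand-in for consumed differential-analysis output). Gene
#' tables carry the generator's logistic-model DE status with consistent
#' reported statistics plus negative-binomial replicate counts. Loop lists
#' and Poisson binned coverage for broad marks are also produced.
#'
#' @param truth A \code{sim_truth}.
#' @param seed Integer seed.
#' @param chip_cv Replicate coefficient of variation for peak intensities.
#' @return List with \code{peaks} (ctcf/h3k27ac/rad21 data frames),
#'   \code{genes}, \code{loops_high}, \code{loops_low}, \code{marks} and
#'   \code{mark_bins}.
#' @export
simulate_feature_tables <- function(truth, seed = 1L,
                                    chip_cv = truth$config$chip_cv) {
  set.seed(as.integer(seed))
  cfg <- truth$config
  nr <- cfg$chip_reps
  sdlog <- if (chip_cv > 0) sqrt(log(1 + chip_cv^2)) else 0

  peak_table <- function(tp) {
    n <- nrow(tp)
    out <- tp[, c("chrom", "start", "end", "feature_id")]
    hi <- matrix(tp$mean_high, n, nr) * exp(matrix(
      stats::rnorm(n * nr, 0, sdlog), n, nr))
    lo <- matrix(tp$mean_low, n, nr) * exp(matrix(
      stats::rnorm(n * nr, 0, sdlog), n, nr))
    colnames(hi) <- sprintf("high_%d", seq_len(nr))
    colnames(lo) <- sprintf("low_%d", seq_len(nr))
    out <- cbind(out, hi, lo)
    out$log2fc <- log2(rowMeans(hi) / rowMeans(lo))
    pv <- vapply(seq_len(n), function(i) {
      a <- log2(hi[i, ]); b <- log2(lo[i, ])
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }, numeric(1))
    out$pvalue <- pv
    out$qvalue <- stats::p.adjust(pv, method = "BH")
    out
  }
  peaks <- lapply(truth$peaks, peak_table)

  g <- truth$genes
  genes <- g[, c("chrom", "start", "end", "gene_id", "strand", "tss")]
  genes$log2fc <- g$true_log2fc
  genes$qvalue <- g$true_qvalue
  genes$de_flag <- abs(genes$log2fc) > cfg$de_lfc & genes$qvalue < cfg$de_q
  nrr <- cfg$rna_reps
  mu_hi <- g$nb_mu * 2^(g$true_log2fc / 2)
  mu_lo <- g$nb_mu * 2^(-g$true_log2fc / 2)
  size <- 1 / cfg$nb_dispersion
  ch <- matrix(stats::rnbinom(nrow(g) * nrr, mu = rep(mu_hi, nrr), size = size),
               ncol = nrr)
  cl <- matrix(stats::rnbinom(nrow(g) * nrr, mu = rep(mu_lo, nrr), size = size),
               ncol = nrr)
  colnames(ch) <- sprintf("count_high_%d", seq_len(nrr))
  colnames(cl) <- sprintf("count_low_%d", seq_len(nrr))
  genes <- cbind(genes, ch, cl)

  loop_out <- function(base, extra) {
    out <- rbind(base[, c("chrom", "start1", "end1", "start2", "end2", "name")],
                 if (nrow(extra)) extra[, c("chrom", "start1", "end1",
                                            "start2", "end2", "name")])
    out$qvalue <- stats::runif(nrow(out), 0, 0.009)
    out$count <- stats::rpois(nrow(out), 40)
    out[order(out$start1, out$start2), ]
  }
  loops_high <- loop_out(truth$loops$common, truth$loops$unique_high)
  loops_low <- loop_out(truth$loops$common, truth$loops$unique_low)

  # broad marks: Poisson coverage on the compartment grid, label-dependent
  bins <- truth$bins_comp
  mids <- (bins$start + bins$end) / 2
  nm <- cfg$mark_reps
  mark_counts <- function(active_label) {
    hi <- ifelse(comp_label_at(truth, mids, "high") == active_label, 100, 50)
    lo <- ifelse(comp_label_at(truth, mids, "low") == active_label, 100, 50)
    m <- cbind(matrix(stats::rpois(length(mids) * nm, rep(hi, nm)), ncol = nm),
               matrix(stats::rpois(length(mids) * nm, rep(lo, nm)), ncol = nm))
    colnames(m) <- c(sprintf("high_%d", seq_len(nm)),
                     sprintf("low_%d", seq_len(nm)))
    m
  }
  marks <- list(h3k36me2 = mark_counts("A"), h3k27me3 = mark_counts("B"))

  list(peaks = peaks, genes = genes, loops_high = loops_high,
       loops_low = loops_low, marks = marks, mark_bins = bins)
}

# covariate construction shared by the generator and the linkage model
design_covariates <- function(genes, diff_ctcf, diff_k27ac, tads, loops) {
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    k27ac.tad = 0L, ctcf.tad = 0L,
                    k27ac.loop = 0L, ctcf.loop = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(tads) > 0L) {
    gt <- containment_hits(genes, tads)
    flag_tads <- function(pk) {
      if (nrow(pk) == 0L) return(integer(0))
      unique(containment_hits(pk, tads)$domain)
    }
    ct <- flag_tads(diff_ctcf)
    kt <- flag_tads(diff_k27ac)
    out$ctcf.tad[unique(gt$feature[gt$domain %in% ct])] <- 1L
    out$k27ac.tad[unique(gt$feature[gt$domain %in% kt])] <- 1L
  }
  if (!is.null(loops) && nrow(loops) > 0L) {
    span <- data.frame(chrom = loops$chrom, start = loops$start1,
                       end = loops$end2)
    gl <- promoter_hits(genes, span)
    flag_loops <- function(pk) {
      if (nrow(pk) == 0L) return(integer(0))
      unique(overlap_hits(pk, span)$domain)
    }
    cl <- flag_loops(diff_ctcf)
    kl <- flag_loops(diff_k27ac)
    out$ctcf.loop[unique(gl$feature[gl$domain %in% cl])] <- 1L
    out$k27ac.loop[unique(gl$feature[gl$domain %in% kl])] <- 1L
  }
  out
}
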