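#' Build the per-gene binary design for the linkage model
#'
#' One row per gene with the outcome \code{gene.de} and four binary
#' covariates indicating whether the gene shares a TAD (full containment) or
#' a CTCF loop (promoter window vs loop span) with at least one differential
#' CTCF or H3K27ac peak. Differential peaks are pre-filtered at the supplied
#' thresholds. Domains should be the union over both conditions; genes inside
#' no domain get all-zero covariates.
#'
#' @param genes Gene table with \code{tss}, \code{strand}, \code{log2fc},
#'   \code{qvalue} and/or \code{de_flag}.
#' @param ctcf_peaks,k27ac_peaks Peak tables with \code{log2fc},
#'   \code{qvalue}.
#' @param tads TAD intervals (union of conditions).
#' @param loops Loop table (union or common set across conditions).
#' @param peak_lfc,peak_q Differential-peak thresholds.
#' @param de_lfc,de_q Gene DE thresholds, used when \code{de_flag} is absent.
#' @return Data frame with columns \code{gene_id}, \code{gene.de},
#'   \code{k27ac.tad}, \code{ctcf.tad}, \code{k27ac.loop}, \code{ctcf.loop}.
#' @export
build_design <- function(genes, ctcf_peaks, k27ac_peaks, tads, loops,
                         peak_lfc = 1, peak_q = 0.01,
                         de_lfc = 1, de_q = 0.01) {
  if (nrow(genes) == 0L) stop("empty gene table")
  diff_peaks <- function(pk) {
    pk[abs(pk$log2fc) > peak_lfc & pk$qvalue < peak_q, , drop = FALSE]
  }
  X <- design_covariates(genes, diff_peaks(ctcf_peaks),
                         diff_peaks(k27ac_peaks), tads, loops)
  de <- if ("de_flag" %in% names(genes)) genes$de_flag else
    abs(genes$log2fc) > de_lfc & genes$qvalue < de_q
  data.frame(gene_id = genes$gene_id, gene.de = as.integer(de),
             X[, c("k27ac.tad", "ctcf.tad", "k27ac.loop", "ctcf.loop")],
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Fit the logistic linkage model
#'
#' Maximum-likelihood logistic regression of \code{gene.de} on the four
#' binary covariates (optionally with CTCF x H3K27ac interaction terms),
#' with Wald z statistics and two-sided normal p-values per coefficient.
#'
#' @param design Output of [build_design()].
#' @param include_interaction Add \code{k27ac.tad:ctcf.tad} and
#'   \code{k27ac.loop:ctcf.loop} terms.
#' @return List of class \code{linkage_glm}: \code{coefficients} (term,
#'   estimate, se, z, p), \code{loglik}, \code{n}, \code{converged},
#'   \code{separation}, and the underlying \code{fit}.
#' @export
fit_logistic <- function(design, include_interaction = FALSE) {
  y <- design$gene.de
  if (length(unique(y)) < 2L)
    stop("outcome has no variation; model cannot be fitted")
  form <- if (include_interaction)
    gene.de ~ k27ac.tad + ctcf.tad + k27ac.loop + ctcf.loop +
      k27ac.tad:ctcf.tad + k27ac.loop:ctcf.loop
  else
    gene.de ~ k27ac.tad + ctcf.tad + k27ac.loop + ctcf.loop
  fit <- stats::glm(form, family = stats::binomial(), data = design,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) stop("IRLS did not converge")
  s <- summary(fit)$coefficients
  mu <- stats::fitted(fit)
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (separation)
    warning("possible complete separation; coefficients may be unstable")
  structure(list(
    coefficients = data.frame(term = rownames(s), estimate = s[, 1],
                              se = s[, 2], z = s[, 3], p = s[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(design), converged = fit$converged,
    separation = separation, fit = fit),
    class = "linkage_glm")
}

#' @export
print.linkage_glm <- function(x, ...) {
  cat(sprintf("Logistic linkage model (n = %d, logLik = %.2f)\n",
              x$n, x$loglik))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Clustering fractions of expression and chromatin changes
#'
#' Reports (a) the fraction of DE genes sharing a domain with at least one
#' differential peak (any nonzero covariate), (b) the fraction of TADs
#' containing both a DE gene and a differential peak, and (c) the same for
#' loops.
#'
#' @param design Output of [build_design()].
#' @param genes,tads,loops Tables used to build the design.
#' @param diff_ctcf,diff_k27ac Differential peak tables (pre-filtered).
#' @return List with \code{frac_de_genes_linked}, \code{frac_tads},
#'   \code{frac_loops}.
#' @export
summarize_linkage <- function(design, genes, tads, loops,
                              diff_ctcf, diff_k27ac) {
  de <- design$gene.de == 1
  linked <- rowSums(design[, c("k27ac.tad", "ctcf.tad",
                               "k27ac.loop", "ctcf.loop")]) > 0
  frac_a <- if (any(de)) mean(linked[de]) else 0
  dpk <- rbind(diff_ctcf[, c("chrom", "start", "end")],
               diff_k27ac[, c("chrom", "start", "end")])
  de_genes <- genes[de, , drop = FALSE]
  frac_dom <- function(domains, loop = FALSE) {
    if (is.null(domains) || nrow(domains) == 0L) return(0)
    if (loop) {
      span <- data.frame(chrom = domains$chrom, start = domains$start1,
                         end = domains$end2)
      g <- unique(promoter_hits(de_genes, span)$domain)
      p <- unique(overlap_hits(dpk, span)$domain)
    } else {
      g <- unique(containment_hits(de_genes, domains)$domain)
      p <- unique(containment_hits(dpk, domains)$domain)
    }
    length(intersect(g, p)) / nrow(domains)
  }
  list(frac_de_genes_linked = frac_a,
       frac_tads = frac_dom(tads),
       frac_loops = frac_dom(loops, loop = TRUE))
}
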