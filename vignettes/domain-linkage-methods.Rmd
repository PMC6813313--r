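---
title: "Methods: differential 3D-genome analysis within insulated domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential 3D-genome analysis within insulated domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadlink)
```

## Scope

`tadlink` compares chromosome organization and chromatin state between two
conditions with replicated data. Its stages are: ICE balancing of binned
intra-chromosomal contact matrices; ratio insulation scoring with TAD and
boundary calling; differential mean boundary scores (MBS) with CTCF/Rad21
boundary occupancy; common-TAD identification and an intra-TAD
interaction-change statistic; A/B compartment eigenvectors, saddle plots and
two compartmentalization-strength metrics; compartment-switch detection;
domain-level integration of peak and expression fold changes; and a logistic
regression linking differential expression to chromatin changes shared
within TADs and CTCF loops. A synthetic-data module generates every input
with known ground truth, so each stage is validated end to end without
external downloads. Upstream read-level processing (alignment, peak calling,
count-level differential testing, loop significance modeling) is out of
scope: the package consumes their tabular outputs.

## Matrix normalization

Contact matrices arrive as a bins BED plus upper-triangular `i j count`
triplets (0-based bin indices). `ice_normalize()` masks zero-coverage bins
plus the lowest 2% of nonzero-coverage bins (`mask_low_frac`, following
common pipeline defaults), then iteratively rescales rows and columns until
the unmasked marginals agree to a relative tolerance of `1e-5` (at most 200
iterations). The balanced matrix is rescaled to the input total so that
count-scale statistics keep their magnitude.

Two choices matter downstream:

* **Shared masks for comparisons.** Whenever two samples are compared bin by
  bin (differential insulation, the intra-TAD change), all matrices are
  balanced under the union of their coverage masks. Masks that differ by
  even a few bins make the bias estimates locally incomparable and can
  produce artifactual changes next to the divergent bins.
* **Count scale for insulation, common scale for intensities.** The ratio
  insulation score uses a pseudocount of 1 and is therefore computed on
  balanced matrices at their native totals, where it is effectively
  scale-invariant. The intra-TAD change statistic compares absolute
  intensities, so its two inputs are additionally scaled to a common total
  (`1e6` by default).

The expected (distance-decay) model used for observed/expected transforms is
the per-distance arithmetic mean over unmasked pairs, per chromosome. Empty
strata and masked bins give missing values, never zeros.

## Insulation, boundaries, and the MBS test

For bin $i$ and window $w$ (default: 500 kb worth of bins, i.e. 12 bins at
40 kb), let $L$ and $R$ be the total contacts among the bins $[i-w, i]$ and
$[i, i+w]$, and $X$ the contacts between the two flanks. The ratio score is
$(L + R + 1)/(2X + 1)$; higher means stronger insulation. Near masked bins
each window sum is rescaled by its fraction of valid bin pairs, and bins
with under half of their window pairs valid are missing — without this,
zeroed rows fake insulation peaks.

Boundary regions are maximal runs of bins scoring at or above the
chromosome mean that contain a peak above mean $+ k\,$sd ($k = 0.5$,
exposed in the configuration). On the synthetic studies this yields
multi-bin regions with a median of about 7 bins, matching the scale
reported for ChIP-grade Hi-C boundary calls. TADs span between the peak
centers of consecutive boundaries, so adjacent TADs abut at the point of
strongest insulation. A flat track yields one whole-chromosome TAD and no
boundaries.

The MBS of a boundary is the arithmetic mean of the ratio scores inside its
region. Differential testing pools all per-bin, per-replicate scores inside
each reference-condition boundary and applies a two-sided unpaired t-test.
The pooled-variance (Student) form is used so the statistic equals the
textbook two-sample formula; zero-variance pools get $p = 1$ with a
warning. BH correction runs across all boundaries (genome-wide), and
significance defaults to $|\log_2\mathrm{FC}| > 0.1$ and FDR $< 0.05$. Peak
occupancy assigns CTCF/Rad21 peaks to boundary regions extended by one bin
on either side (any overlap > 0 bp), aggregates assigned intensities per
replicate, and tests them with the same pooled t-test.

## Common TADs and the intra-TAD change

TADs shorter than 10 bins (400 kb at 40 kb) are discarded. Two TADs are
positionally consistent when both boundaries lie within 3 bins (120 kb);
candidate search extends each TAD by 3 bins per side. A matched pair forms a
common TAD spanning the larger extent. Multiple matches are resolved by the
smallest summed boundary distance with a leftmost tie-break (the upstream
method leaves this case open), and matching is symmetric in argument order.

For each common TAD the statistic is the difference of mean interaction
intensities over all intra-TAD bin pairs ($i \le j$, diagonal included,
both bins unmasked in both samples), second sample minus first, with a
paired two-sided t-test over the per-pair differences, BH across TADs, and
classification Gain/Loss/Stable at FDR $< 0.1$ and $|\Delta| > 0.3$ (both
exposed; a stricter FDR of 0.05 is sometimes used for display-level calls).
TADs with fewer than three usable pairs are flagged untestable.

## Compartments

At 50 kb resolution, each chromosome's balanced matrix is transformed to
observed/expected, a Pearson correlation matrix is computed over unmasked
bins, and the first eigenvector (PC1) is taken. The sign is oriented so that
bins holding at least one active-mark (H3K27ac) peak average positive; A
means PC1 > 0. Switching uses, per bin, the Pearson correlation between its
cis interaction-profile rows in the two conditions: a bin switches when its
PC1 sign flips *and* the profile correlation falls below 0.4 (the threshold
is exposed; the upstream tool prints no value). Adjacent switching bins of
one class merge into AB (A in the reference, B in the other condition) or
BA regions.

Saddle analysis ranks unmasked bins by ascending PC1 into 50 as-equal-as-
possible groups and reports the log2 mean observed/expected between all
group pairs. Corner aggregates average the linear-scale block means over the
strongest 20% of ranks, and two strength metrics are computed on the linear
scale: $\sqrt{AA \cdot BB / AB^2}$ and
$\mathrm{median}(AA \cup BB)/\mathrm{median}(AB \cup BA)$. The same corner
rule is applied to both metrics (the source for the first prints no corner
size). Both are invariant to relabeling A and B.

## Domain integration

Peaks and genes are assigned to compartment regions and common TADs by full
containment; to loops by any overlap with the full span from anchor1 start
to anchor2 end, except genes, which use the strand-respecting 5 kb
upstream-of-TSS promoter window. Per-domain mean log2 fold changes are
computed either over all assigned features or only the differential subset
(q < 0.05 by default); domains missing any feature type are excluded from
correlation analysis. Broad marks (H3K36me2, H3K27me3) are quantified as
binned counts, normalized with median-of-ratios size factors across all
replicates, and summarized as log2 ratios of condition means with a
pseudocount of 1. Loops match between conditions when both anchor pairs
overlap (> 0 bp), resolving multi-matches by maximal summed anchor overlap.
Per-TAD compartment change is the difference of mean PC1 (50 kb bins whose
midpoint falls in the TAD; the two grids are reconciled by bin midpoint)
plus bp overlap with switch regions. Domains are classed positive/negative
when every included feature mean shares a sign, and pairwise Pearson
correlations are reported. Peak-gene annotation labels a peak `promoter`
when it overlaps any TSS ± 3 kb, otherwise `distal` toward genes with TSS
within (3 kb, 250 kb], otherwise `unassigned`.

## The logistic linkage model

Each gene contributes one row with outcome `gene.de` and four binary
covariates: whether the gene shares a TAD (`*.tad`) or a CTCF loop
(`*.loop`) with at least one differential CTCF or H3K27ac peak. Genes map
to TADs by full containment and to loops through the promoter window, the
same rules as the integration stage; domains are the union over both
conditions. Differential peaks default to $|\log_2\mathrm{FC}| > 1$ and
q < 0.01 — the peak-level thresholds used throughout — and are exposed in
the configuration. The model

```
glm(gene.de ~ k27ac.tad + ctcf.tad + k27ac.loop + ctcf.loop,
    family = binomial())
```

is fitted by maximum likelihood (IRLS, convergence `1e-8`, up to 50
iterations) with Wald z tests per coefficient; optional CTCF x H3K27ac
interaction terms can be added. Complete separation is flagged and reported
rather than silently regularized. Summary fractions report how many DE
genes share a domain with a differential peak, and how many TADs and loops
contain both.

## The synthetic study

The generator plants every effect the pipeline is meant to recover, on one
synthetic chromosome (defaults: 20 Mb, 40 kb TAD grid, 50 kb compartment
grid, two Hi-C replicates per condition at 2e6 read pairs, three ChIP
replicates with CV 0.1, 400 genes):

* **Contact maps.** Expected counts follow a $(s+1)^{-1}$ power-law decay
  times planted factors, and observed counts are Poisson (the standard
  model for read-pair counts at fixed expectation). TADs partition the
  chromosome (25 TADs, so a mean length of 800 kb) with intra-TAD
  enrichment 2.0; "Gain" TADs multiply this by 1.5 in the high condition.
* **Boundaries** are extended insulator zones (±3 bins around the
  junction): every contact whose span intersects the zone is multiplied by
  the condition's attenuation (0.5 by default), while contacts entirely
  inside the zone stay intact. This produces plateaus of elevated ratio
  scores about 7 bins wide — the scale real boundary calls show — rather
  than single-bin needles. A strengthened boundary divides the attenuation
  (factor 2 by default) in the high condition.
* **Compartments** are alternating A/B blocks whose sizes vary around 1 Mb
  (0.6-1.4x on the 50 kb grid). The irregular sizes matter: on a strict
  lattice, label agreement correlates with genomic distance and the decay
  expectation absorbs most of the compartment contrast. Same-label pairs
  are multiplied by $(1+\gamma)$, cross-label by $(1-\gamma)$, $\gamma =
  0.4$, giving a closed-form target of $(1+\gamma)/(1-\gamma) \approx 2.33$
  for the strength metrics. Planted flips relabel one interior block of
  exactly 1 Mb in the high condition.
* **Visibility.** Per-bin lognormal visibility factors (sd 0.25, 1% of bins
  near-invisible) multiply both fragment ends. They give ICE real work and
  make the low-coverage mask remove mappability holes instead of eating the
  (coverage-depressed) boundary bins.
* **Peaks** get lognormal intensities around condition means (differential
  subsets shift by log2 fold change 2); reported log2FC/q-values come from
  a two-sample t-test on log2 replicate intensities with BH — a stand-in
  for the consumed differential tables, which are produced upstream in real
  use. H3K27ac peaks concentrate (80%) in stable A compartments so the PC1
  orientation rule has signal; CTCF peaks sit at boundary junctions and
  anchor the loop lists (spans lognormal around 200 kb, the scale of
  CTCF-anchored loops).
* **Genes.** DE status is drawn Bernoulli(logistic($X\beta$)) with $\beta =
  (-2, 1.0, 0.8, 0.6, 0.9)$ and covariates computed from the planted
  domains by the same assignment rules the pipeline uses. Reported
  log2FC/q-values are generated consistently with the drawn flag (the flag
  equals the thresholded reported statistics by construction), and
  negative-binomial replicate counts (dispersion 0.1) are emitted
  alongside. Genes inside chromatin-altered TADs inherit that TAD's fold-
  change direction, which co-plants expression and chromatin changes in the
  same domains.

What the generator does **not** emulate: restriction-fragment structure,
trans contacts, copy-number or GC trends, spatially autocorrelated ChIP
background, and the count-level machinery of the consumed differential
tables. Passing tests therefore demonstrate that the implementation
recovers planted effects of realistic magnitude under Poisson/lognormal
noise at desk scale — not that any specific biological dataset would yield
the same counts.

## Problem sizes and numerical choices

Validation studies use one chromosome per scenario: 160 Mb (4000 bins) for
the boundary-power study (201 TADs, 20 strengthened boundaries, two
replicates at 5e6 pairs — comparable to the per-160 Mb share of a typical
Hi-C library), 80 Mb for the intra-TAD study (100 TADs, mean 20 bins, so
called TADs clear the 10-bin filter comfortably), and 20 Mb at 50 kb for
compartment scenarios. Logistic-model calibration uses 10,000 genes, 100
regenerated studies for CI coverage and 500 outcome redraws for type-I
error. Tie-breaks, degenerate inputs (flat tracks, zero-variance pools,
constant outcomes, all-zero matrices) and their handling are stated in the
respective sections; every such rule is unit-tested.

## Known limitations

Single-chromosome synthetic studies cannot probe genome-wide FDR behavior
across heterogeneous chromosomes. The ratio-insulation formula follows the
published description of the upstream tool-chain qualitatively (higher =
more insulated) but is an interpretation, as the exact formula is not
printed in the sources available to this package; likewise the
interaction-profile correlation rule for switching. The boundary caller is
a mean/sd run-based design, not a faithful port of the delta-vector
algorithm it stands in for. Loop lists are consumed, never called, and the
pooled unpaired t-test for boundaries deliberately ignores the pairing of
bins across conditions because that is how the method is defined.
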