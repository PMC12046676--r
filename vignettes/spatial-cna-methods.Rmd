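---
title: "Inferring spatial copy number alterations from dense spot-based data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spatial copy number alterations from dense spot-based data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spot-based spatial transcriptomics assays with small, densely packed capture
beads (Slide-seq and similar platforms) resolve tumour architecture at
near-cellular scale, but each bead captures very few transcripts — typically
a few hundred UMIs. Expression-based copy number inference, which looks for
contiguous shifts in expression along each chromosome relative to a
non-malignant reference, is badly underpowered at that depth. `spotcna`
addresses this with a *spatio-molecular binning* step: neighbouring beads
with similar expression are merged into bins before copy number alteration
(CNA) scoring, trading a little spatial resolution for a large gain in
counts, and therefore signal.

The pipeline stages are:

1. **Filtering.** Genes with ≤ 300 total counts are removed, and low-quality
   beads (< 100 counts) are removed conservatively — in ascending count
   order, only until the surviving fraction of such beads is at most 35%.
   Beads with zero counts are always removed: they carry no information and
   make the per-bead count normalisation undefined.
2. **Log expression.** Each bead is scaled to counts-per-million (UMI data
   carries no gene-length bias, so no length term) and transformed with
   `log2(x + 1)`. Each gene is centred on its mean over the *reference*
   beads (those annotated non-malignant and trusted as copy-neutral), and
   values are capped at ±3 so no single gene dominates. Mitochondrial and
   Y-chromosome genes are then removed and genes are put in genomic order.
3. **Chromosomal smoothing.** Within each chromosome, expression is smoothed
   with a pyramidal weighted moving average: the window around gene *i*
   covers its *m* = (*k* − 1)/2 neighbours on each side (default
   *k* = 101, reduced to the chromosome's gene count when smaller), and
   gene *j* in the window gets raw weight *m* + 1 − |*i* − *j*|,
   normalised to sum to one. At chromosome ends the pyramid is truncated to
   the genes that exist; the weights renormalise over the truncated window.
4. **Re-centring and rescaling.** Each bead is centred by its own mean
   smoothed intensity, creating a per-bead baseline of zero intensity
   change. This step doubles as a library-size correction: with sparse
   counts, `log2(CPM + 1)` acquires a depth-dependent additive offset per
   bead, and without per-bead centring that offset — not copy number —
   dominates all downstream distances. The reference-bead mean is then
   subtracted per gene and the log reversed (`2^x`), giving relative
   expression intensities with copy-neutral ≈ 1.
5. **Spatio-molecular binning.** Separately within the malignant and
   non-malignant populations, beads are clustered with Ward's method
   (ward.D2) on the pseudo-distance
   `X_pseudo = k_spatial * X_spatial + k_expression * X_expression`,
   where `X_spatial` is the Euclidean distance between bead coordinates
   (µm) and `X_expression` the Euclidean distance between intensity rows.
   Defaults `k_spatial = 55`, `k_expression = 1` prioritise spatial
   proximity; with `spatial = FALSE` (dissociated data) the spatial term is
   omitted. The tree is cut into `round(n / 12)` bins per population. Bin
   intensity is the unweighted mean over member beads, bin coordinates the
   mean coordinates, bin UMI the summed member UMI, and bin type the mode
   of member types (ties broken by label sort order).
6. **CNA scores.** Bin intensities are clamped to [0.6, 1.4]; 1 is copy
   neutral, above 1 amplification, below 1 deletion.
7. **Clone calling.** Malignant bins are Ward-clustered on the Euclidean
   distance between their CNA score rows; the number of clones
   `k_malignant` is chosen from 2–10 by maximising the mean silhouette
   width. The total number of clusters is `k_all = k_malignant + 1`, with
   one cluster holding the non-malignant population.
8. **Differential expression.** Beads inherit their bin's cluster; each
   gene is tested one-vs-rest per cluster with a negative binomial GLM on
   raw counts (log total-UMI offset, cluster indicator), Wald p-values,
   Bonferroni correction across all gene × cluster tests.
9. **Arm profiles and concordance.** Gene-level CNA scores are averaged per
   chromosome arm (centromere tables for hg38 and hg19 ship with the
   package), and profiles from different sources are compared by Spearman
   rank correlation restricted to arms carrying signal in both profiles.

# Design choices where the method description is open

**UMI adjustment of bin scores.** Bin intensities could be further adjusted
for sequencing depth. We examined a shrinkage of deviations toward 1 for
below-median-UMI bins (`umi_adjust = "shrink"`) and found it
counterproductive as a default: sparse counts already attenuate the
log-space deviations of shallow beads, and malignant tissue regions tend to
be less cell-dense than the reference compartment, so shrinking low-UMI
bins again preferentially erases malignant signal (on simulated data, clone
recovery accuracy drops from ≈0.9 to ≈0.7). The default is therefore
`umi_adjust = "none"`, with the shrinkage retained as an option for
sensitivity analyses.

**Clone assignment.** Silhouette model selection runs on the malignant-bin
tree, so the default assignment (`method = "malignant_tree"`) cuts that
same tree into `k_malignant` clones and places the entire non-malignant
population in the (k+1)-th cluster — one cluster is assigned to the
non-malignant population by construction. The Ward cut is refined by a
single nearest-centroid (k-means) pass: when the two clone signatures
differ in magnitude, the Ward boundary between them is biased toward the
weaker signature, whereas the nearest-centroid boundary sits at the 50:50
mixture point for near-orthogonal signatures. The alternative
(`method = "joint"`) re-clusters all bins jointly into `k_all` clusters and
designates the cluster with the highest non-malignant fraction as normal;
on simulated data with intermixed normals it tends to absorb weak-signal
malignant bins into the normal cluster, so it is not the default.

**Pseudo-distance clustering.** The combined pseudo-distance matrix is fed
directly to Ward linkage as the dissimilarity; distances use raw µm and raw
intensity units with no standardisation, matching the stated linear
combination. The alternative reading — Euclidean distances between rows of
the pseudo-distance matrix — would be a double distance and is not used.

**Ties and determinism.** Bin-type ties break by label sort order;
silhouette ties pick the smallest `k`; `round(n/12)` uses R's
round-half-to-even; bead-filter ties break by bead id. All inference stages
are deterministic; a single seed governs the stochastic steps (simulation,
thinning, stochastic rounding).

**Silhouette metric.** The silhouette is computed with the same Euclidean
metric as the clustering.

**Arm signal threshold.** An arm "carries signal" when its mean CNA score
deviates from 1 by at least 0.02. The threshold is configurable and
recorded in the concordance output.

# The simulator

`simulate_slideseq()` emulates bead capture on a square field (default
3000 × 3000 µm, matching a 3 mm puck):

* **Cell profiles.** Per-gene negative binomial counts with log-normally
  distributed means (meanlog 0, sdlog 1) and dispersion 0.5 — a generic
  single-cell-like profile. Two malignant clones carry arm-level fold
  changes (default: four disjoint altered arms each, amplification 1.5 or
  deletion 0.5); normal cells are copy neutral. A real cell × gene matrix
  with clone labels can be substituted, in which case cells are resampled
  with replacement.
* **Placement.** Defaults place 6000 normal cells either in the top tenth
  of the field (`separated`) or across it (`mixed`), and 7000 cells per
  clone in 100 vertical zones whose clone1:clone2 ratio steps down in 1%
  decrements (99:0, 98:1, …, 0:99), creating opposing spatial gradients.
* **Beads.** Beads at random integer coordinates receive the
  Gaussian-kernel-weighted sum of nearby cell profiles (kernel sd
  `1500 * sqrt(1/total_cells)` µm, truncated at 3 sd), rounded
  stochastically to integers so expectations are preserved. Per-bead clone
  weight fractions and the dominant clone are recorded as ground truth;
  beads capturing no cell are dropped.
* **Thinning.** `downsample()` applies per-entry binomial thinning to
  emulate lower capture efficiency.

What the simulator does *not* model: bead barcode errors, spatially varying
capture efficiency, cell segmentation effects, transcriptional
heterogeneity within a clone beyond NB noise, or realistic gene-length and
GC effects. Passing the recovery tests therefore demonstrates the
pipeline's behaviour under idealised sparsity and spatial mixing, not
performance on any particular tissue.

# Validation scale and expectations

The package's validation suite runs at desk scale: 1000 genes on 10
chromosomes, 2000 beads, 1200 normal cells and 1400 cells per clone (the
full-scale design scaled by one fifth), with the kernel width following the
`1500 * sqrt(1/total_cells)` rule. At 10% thinning this yields a median of
roughly 200 UMIs per bead, comparable to real Slide-seq depth. Under these
conditions the suite checks that:

* smoothing equals a naive double-loop oracle to 1e-10 and all weight
  vectors sum to 1;
* a CNA-free, all-reference dataset yields intensities and bin scores with
  median within 1 ± 0.05, all scores inside [0.6, 1.4];
* with two implanted clones (separated scenario, 10% thinning) silhouette
  selects k = 2, bin-level clone accuracy is ≥ 0.9 after optimal label
  matching, all altered arms deviate in the implanted direction, and the
  inferred arm profile correlates with truth at Spearman ρ ≥ 0.8;
* the intermixed-normal scenario still resolves both clones (accuracy
  ≥ 0.75, below the separated case);
* recovery survives 25% and 10% thinning and degrades monotonically toward
  2%, where the malignant population no longer survives quality filtering
  — a faithful failure mode of extremely shallow data (the bead filter
  keeps the deepest beads, which sit in the densest, normal-dominated
  regions);
* the NB differential expression test is calibrated (type-I error within
  the binomial interval of nominal 0.05 over 1000 null genes) and powered
  (≥ 95% of 4-fold effects detected at 200 beads per group after
  Bonferroni);
* binomial thinning preserves expected totals within three standard
  deviations.

For the downsampling comparison, one base dataset is simulated at full
depth and thinned to each fraction, mirroring a sensitivity analysis on a
fixed dataset; re-simulating the field per fraction would add between-run
variance unrelated to depth.

Known limitations: the method requires whole-transcriptome counts and a
trusted non-malignant reference annotation; it assumes CNAs manifest as
coherent expression shifts over ~100-gene windows, so focal events are
invisible; bins mixing beads from regions where two clones interleave below
bin resolution receive intermediate profiles and are assigned to whichever
clone dominates; and the dense per-population distance matrices target
datasets up to a few tens of thousands of beads.
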