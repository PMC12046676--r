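# spotcna

Inference of copy number alterations (CNAs) and malignant clones from
sparse, high-density spot-based spatial transcriptomics data
(Slide-seq-like beads), for tumour biologists working with spatial
expression data and a non-malignant reference annotation.

Each bead on such platforms captures only a few hundred UMIs — far too few
to call CNAs per bead from expression. `spotcna` recovers the signal by
**spatio-molecular binning**: after reference-centred, chromosome-smoothed
expression intensities are computed per bead, beads are merged into bins by
Ward clustering of the pseudo-distance

```
X_pseudo = k_spatial * X_spatial + k_expression * X_expression
```

(`X_spatial`: Euclidean distance between bead coordinates in µm;
`X_expression`: Euclidean distance between expression intensity rows;
defaults `k_spatial = 55`, `k_expression = 1`). Per-gene smoothing uses a
pyramidal weighted moving average along each chromosome (window `k = 101`
genes, weight `m + 1 − |i − j|` for gene `j` around centre `i`,
`m = (k−1)/2`, normalised to sum to 1). Bin intensities are clamped to
`[0.6, 1.4]` to give CNA scores (1 = copy neutral, >1 amplification,
<1 deletion). Malignant bins are clustered into clones, the clone number
`k_malignant ∈ 2..10` chosen by maximising the mean silhouette width, with
one extra cluster for the non-malignant population. Clusters are compared
by negative-binomial differential expression (Bonferroni-corrected) and by
Spearman correlation of chromosome-arm mean CNA scores.

The package also ships an in silico bead simulator (Gaussian-kernel
aggregation of cell profiles with implanted arm-level CNAs, opposing clone
gradients, and binomial downsampling) so the entire pipeline can be
exercised and validated without any external dataset.

## Worked example

Simulate a 2000-bead dataset with two clones (four altered arms each,
fold changes 1.5/0.5), normals spatially separated, thinned to 10% depth,
and run the full pipeline:

```r
library(spotcna)

cfg <- sim_config(n_beads = 2000, n_normal_cells = 1200,
                  n_malignant_per_clone = 1400, n_genes = 1000,
                  scenario = "separated", downsample_fraction = 0.1,
                  seed = 1)
sim <- simulate_slideseq(cfg)
run <- run_pipeline(sim$se, sim$gene_positions,
                    run_config(run_dge = FALSE), out_dir = "out")
run
#> cna_run: 1992 beads, 166 bins, k_malignant = 2
round(run$clones$silhouette_trace, 3)
#>     2     3     4     5     6     7     8     9    10
#> 0.220 0.118 0.094 0.077 0.075 0.064 0.063 0.063 0.066
```

The silhouette trace peaks at `k = 2`: the two implanted clones are
recovered, plus the non-malignant cluster (`k_all = 3`). Scoring against
the simulator's ground truth:

```r
score <- score_recovery(run, sim)
score$accuracy      # bin-level clone assignment accuracy, optimal matching
#> [1] 0.939759
score$sign_match    # altered arms deviating in the implanted direction
#> [1] 1
round(score$spearman, 3)   # arm-profile concordance with truth, per clone
#> clone1 clone2
#>  0.894  0.894
```

`out/` then contains `bins.tsv`, `cna_scores.tsv`, `silhouette_trace.tsv`,
`arm_profiles.tsv`, `dge.tsv` (when enabled), a YAML run manifest, and
diagnostic PNGs (CNA heatmap with genes in genomic order, spatial cluster
map, arm-profile bars).

A thin command-line wrapper with `simulate`, `run`, `compare`, and `dge`
subcommands is installed at `inst/cli/spotcna.R`.

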