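# methniche

Integrative analysis of radiotherapy-induced epigenetic and transcriptional
remodelling in brain tissue, as one tested R pipeline:

1. **Differential methylation** — per-probe linear models on M-values
   (`M = log2(beta / (1 - beta))`) with covariate adjustment and
   Benjamini–Hochberg control; significant probes merge into differentially
   methylated regions (DMRs) by same-sign runs with bounded gaps.
2. **Genomic annotation and enrichment** — each DMR gets one region class
   (promoter > 5'UTR > 3'UTR > exon > intron > TE > intergenic, midpoint
   rule) and is tested for class enrichment against the array background by
   Fisher exact tests.
3. **Methylation–expression concordance** — DMR genes are intersected with
   differentially expressed genes and classified by the region-dependent
   rule: expression *anti*-correlated with promoter/5'UTR/exon methylation,
   *correlated* with 3'UTR/intron/intergenic methylation.
4. **Bulk deconvolution** — cell-type proportions of bulk methylomes by
   simplex-constrained least squares against a reference atlas.
5. **Spatial niches** — Visium-style spots are QC-filtered, clustered into
   micro-environmental niches (PCA + kNN + Louvain), and deconvolved
   reference-free by latent Dirichlet allocation with held-out-perplexity
   model selection; gene-set activity is scored per spot with
   expression-bin-matched controls.
6. **Receptor–ligand interactions** — for every ordered pair of hex-adjacent
   spots, interaction scores `sqrt(L(sender) * R(receiver))` (complexes via
   the minimum over subunits) are compared between irradiated and control
   conditions with Wilcoxon/BH, directionally, per niche pair.

A first-class synthetic-data module (`simulate_*`) generates every input with
planted ground truth — hypomethylation-biased DMRs, region-coupled expression
shifts, niche-structured spot mixtures, planted directional signalling — so
each stage is verified by planted-truth recovery rather than by fixtures.

The package is written tidyverse-style: tabular results are tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` views,
and everything chains with the pipe.

## Worked example

`run_pipeline()` wires all six stages together on simulated data and returns
a machine-readable report:

```r
library(methniche)
report <- run_pipeline(seed = 1)
report
#> <run_report> seed 1
#>   probes         8000
#>   dmps_q05       417
#>   dmrs           60
#>   pct_hypo       75
#>   dmgs           58
#>   degs           97
#>   overlap        56
#>   concordant     56
#>   spots_kept     512
#>   clusters       8
#>   lda_k          5
#>   rl_tested      956
#>   rl_significant 83
```

Reading the report: of 8000 simulated probes, 417 were significant DMPs
(q < 0.05), merging into 60 DMRs of which 75% were hypomethylated (the
planted bias); the DMRs mapped to 58 genes, 56 of which overlapped the 97
DEGs and all 56 carried a region-consistent (concordant) expression change.
On the spatial side, all 512 spots passed QC, Louvain found 8 spot clusters,
LDA selected K = 5 topics (the planted cell-type number), and 83 of 956
tested receptor–ligand (pair × direction) hypotheses differed significantly
between conditions.

Individual stages compose directly:

```r
ann <- simulate_annotation(n_genes = 100, n_te = 50, seed = 1)
sim <- simulate_methylation(ann, n_probes = 20000, n_dmrs = 100, seed = 2)

dmrs <- call_dmps(sim$data) |>
  call_dmrs(q_thresh = 0.05, maxgap_bp = 1000, min_probes = 3) |>
  annotate_dmrs(ann)

dmr_location_table(dmrs, sim$data$probe_map, ann) |>
  region_enrichment()
```

## Package layout

- `R/sim-*.R` — synthetic-data generators with planted truth
- `R/methylome.R`, `R/deconvolve-bulk.R` — DMP/DMR calling, annotation,
  enrichment, DMG mapping, reference-based deconvolution
- `R/integration.R` — DEGs, DMG∩DEG overlap, concordance rule, methylation
  signatures
- `R/spatial.R`, `R/lda.R` — spot QC, clustering, reference-free
  deconvolution, markers, signature scoring
- `R/rl.R` — adjacency, interaction scoring, condition testing, counting
- `R/pipeline.R` — the orchestrated end-to-end run
- `vignettes/methods.Rmd` — models, assumptions, parameter choices, and
  known limitations
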