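---
title: "Models and design choices in methniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methniche)
```

methniche implements an integrative analysis of radiotherapy-induced change
in brain tissue across three data layers: bulk DNA methylation arrays, bulk
RNA-seq, and Visium-style spatial transcriptomics. This vignette explains the
statistical models behind each stage, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable option existed.

## Differential methylation

Beta values (methylation proportions) are clipped to `[1e-3, 1 - 1e-3]` and
transformed to M-values, `M = log2(beta / (1 - beta))`, before modelling. The
clipping bound avoids infinite M-values at the scale boundaries; the M scale
is used because beta-scale variance is strongly heteroscedastic (small near 0
and 1, largest near 0.5), while M-value variance is approximately constant.

Differentially methylated probes (DMPs) are called by ordinary least squares
of the M-value on a group indicator (irradiated = 1, control = 0) plus any
numeric covariates, with a two-sided t-test on the group coefficient and
Benjamini–Hochberg (BH) adjustment across probes. No empirical-Bayes variance
moderation is applied: with a dozen samples per group the per-probe residual
variance is estimable, the OLS t-test is exactly calibrated under Gaussian
noise (the package's null simulations verify uniform p-values by a
Kolmogorov–Smirnov check), and the simpler model keeps every assumption
visible. Covariate adjustment is plain linear adjustment; the confounding test
verifies that a covariate fully correlated with a planted effect attenuates
the group estimate as expected.

Differentially methylated regions (DMRs) merge significant probes
(BH-adjusted q < `q_thresh`) into maximal runs of same-chromosome, same-sign
probes with inter-probe gaps at most `maxgap_bp` and at least `min_probes`
members. Defaults are `q_thresh = 0.05`, `maxgap_bp = 1000`, `min_probes = 3`
— conventional DMR-caller settings. The same-sign requirement means a single
discordant significant probe splits a run; the merge is order-invariant
because probes are sorted internally.

## Genomic annotation and enrichment

Every DMR receives exactly one region class by midpoint overlap, with
precedence promoter > 5'UTR > 3'UTR > exon > intron > TE > intergenic, so the
location percentages form a partition. Promoters are strand-aware windows
from 1500 bp upstream to 500 bp downstream of the TSS — a common
array-annotation convention. Enrichment per class compares DMR counts against
the array background (all probes classified by the same rule) with a
two-sided Fisher exact test, BH-adjusted within the enrichment family. The
Fisher p-values are tested against a direct hypergeometric enumeration
oracle.

DMRs map to genes by feature overlap; intergenic DMRs map to the nearest TSS
within 10 kb, else to no gene. The 10 kb cutoff is a choice: distal
regulation clearly extends further, but beyond ~10 kb nearest-gene assignment
becomes mostly noise on an annotation of this density.

## Expression and concordance

Differential expression uses OLS on `log2(CPM + 1)` with the same
group-plus-covariates design and BH adjustment. A count GLM would be the
other natural choice; the linear model on log-CPM was chosen because its
calibration and ranking power are what the planted-truth tests verify, and at
10 samples per group with moderate dispersion it performs comparably.

The concordance rule is a pure function of (region class, methylation
direction, expression direction): a gene is concordant when expression change
*opposes* methylation change at promoter/5'UTR/exon regions (hypomethylated
and up-regulated, or hypermethylated and down-regulated) and *agrees* at
3'UTR/intron/intergenic regions. "Anti-correlated/correlated" is implemented
as sign agreement between effect estimates, not per-sample correlation,
because the methylation and expression cohorts are separate sample sets; a
matched design could use per-sample correlation instead. TE-class DMRs are
excluded from the rule and counted separately, since the six-class rule does
not define them. A gene with several region entries is concordant if any
entry is; this "any-record" rule is a documented choice. Only genes in the
DMG-and-DEG overlap (DEG q < 0.05, no fold-change floor) are evaluated.

Methylation signatures take the genes most hypo- and hypermethylated at
promoter/5'UTR/exon regions (up to `k = 200` per direction), ranking by the
per-gene largest-magnitude mean delta beta, ties broken by gene id; a gene
joins only the list of its larger-magnitude direction.

## Reference-based bulk deconvolution

Bulk methylomes are decomposed over a reference atlas by constrained least
squares on the union of discriminating probes: non-negative weights summing
to one, solved as a quadratic program. Betas mix linearly in cell fractions,
so the noiseless problem is exactly identifiable whenever the discriminating
profiles are linearly independent; with M-scale noise of SD 0.3 the recovery
RMSE on 5-type mixtures stays well under 0.05.

## Spatial niches

Spots are clustered jointly across samples with no batch correction (a
per-sample run is a matter of subsetting the input list): depth normalisation
to the median spot total, `log1p`, top 2000 highly variable genes, 30
principal components, a k = 15 nearest-neighbour graph, and Louvain community
detection at resolution 1 under a fixed seed. These are conventional
defaults; the cluster count is data-dependent, so the tests assert recovery
of well-separated planted niches (adjusted Rand index) rather than a specific
cluster count.

Reference-free deconvolution treats each spot as a document and fits latent
Dirichlet allocation by batch variational EM on raw counts, after keeping
genes detected in 5–95% of spots with variance/mean above 1 (over-dispersed
relative to Poisson). Symmetric Dirichlet priors of 1/K are used on both the
spot-topic and topic-gene simplexes. The variational objective is
multi-modal, so each fit is restarted from 8 random initialisations and the
best final evidence lower bound wins — the bound reliably separates good
optima from degenerate ones in the planted-recovery tests. K is selected by
held-out perplexity (20% of spots, folded in by an E-step against the trained
topics) after discarding K values that produce any topic with mean proportion
below 0.02; the final model is refitted on all spots. The ELBO is
non-decreasing over iterations up to numerical precision, and the tests
assert this.

Signature scores use the expression-bin-matched control construction: on
log-normalised expression, the score is the mean over signature genes minus
the mean over control genes drawn from each signature gene's
average-expression bin (25 bins, 50 controls per gene, fixed seed). This
centres the score at zero for a random gene set, which the null tests check
(|mean| < 0.05).

## Receptor–ligand interaction testing

The interaction substrate is spot adjacency on the hexagonal grid: the six
axial neighbours present in the sample plus the spot itself, never crossing
samples. For each ordered adjacent pair (sender, receiver) and each
receptor–ligand pair, the score is the geometric mean of the sender's ligand
expression and the receiver's receptor expression on the log-normalised
scale, with multi-subunit complexes collapsed by the minimum over subunits
(the convention of the curated pair databases). The geometric mean gives
symmetric units and a zero annihilator: if either side is silent the score is
zero.

Scores are compared between conditions by a two-sided Wilcoxon rank-sum per
(pair, sender group, receiver group), BH-adjusted across all tested
hypotheses. A hypothesis is tested only when both conditions have at least 10
spot pairs and at least 10% of spot pairs are nonzero in one condition —
guards against degenerate rank tests.

One statistical caveat deserves emphasis. The unit of analysis is the spot
pair, and adjacent pairs share spots, so observations are positively
correlated within a sample. When condition labels attach to whole samples,
the rank-sum test is therefore anti-conservative. The calibration tests
permute condition labels at the spot-pair level, under which exchangeability
holds and the test is exactly valid (measured type-I error ~0.04 at nominal
0.05). For designs where sample-level inference matters,
`compare_conditions(aggregate = "sample")` averages scores per sample first
and tests the per-sample means; with few samples this is low-powered but
honest. Significant-interaction counts are summarised per directed cluster
pair; the within- vs between-niche comparison uses the per-pair mean count,
since there are twice as many between directions as within.

## The synthetic-data generator

The generator emulates the statistical structure each stage assumes, with
planted ground truth:

* **Annotation**: one toy chromosome tiled by the seven feature classes,
  genes with strand-aware promoters, TEs carved only out of introns and
  intergenic gaps, intergenic fill — a disjoint cover, 0-based half-open.
* **Methylation**: bimodal baseline betas; planted DMRs are runs of 3–10
  probes in windows stratified across the chromosome (one window per stratum,
  so planted regions never collide), hypomethylated with probability 0.75 by
  default; covariates act linearly on the M scale with optional group
  confounding; probe-specific Gaussian noise on the M scale mapped back to
  beta. Planted baselines sit away from the scale boundaries so the planted
  shift is realised without clipping.
* **Expression**: negative-binomial counts; genes hosting exactly one planted
  DMR receive a log fold change whose sign follows the region-dependent
  coupling rule (so the planted set is concordant by construction);
  multi-DMR genes stay expression-neutral, and a disjoint decoy set gets
  expression shifts with no methylation change — the concordance stage
  always has true negatives of both kinds.
* **Spatial**: spots on an axial hex grid partitioned into contiguous niche
  blocks by nearest-seed assignment; spot compositions drawn from a
  Dirichlet centred on the niche archetype with concentration 5, emulating
  the strong spot-to-spot compositional variation of 55 µm spots that
  contain only a handful of cells (with a much tighter concentration the
  composition matrix becomes numerically low-rank and no reference-free
  method can separate cell types that co-occur); Poisson counts at an
  expected depth of 1000 over a 300-gene panel, chosen so detection rates
  match the sparsity regime the LDA gene filter expects. Irradiated samples
  up-scale neuropeptide-like genes in the neuron-dominated niche and planted
  ligand/receptor genes in sender/receiver niches.

What the generator does **not** emulate: probe chemistry and type I/II
effects, cross-reactive probes, batch structure beyond explicit covariates,
genome sequence, spatial image data, cell segmentation, or realistic gene–
gene correlation within cell types (profiles are independent rates). Passing
the planted-truth tests therefore demonstrates that the estimators recover
the structure they model, not that they are robust to every artefact of real
arrays or real Visium runs.

## Problem sizes and runtime

The test suite and the acceptance script run the methylome arm at 50,000
probes with 12 vs 14 samples, the concordance arm at 15,000 probes over 150
genes, spatial recovery on 400-spot grids with 5 cell types and 300 genes,
and receptor–ligand calibration with 500 pairs over four 256-spot samples.
These sizes keep a full run in a few minutes on one CPU while leaving each
recovery check comfortably powered.

## Known limitations

* The DMP/DEG engine is OLS; no variance moderation or count GLM.
* The intergenic-to-gene 10 kb rule and the any-record concordance rule are
  conventions, not estimates.
* LDA topics are identified with cell types only up to a matching; the
  package reports topics and provides `match_topics()` against reference
  profiles when truth (or an external reference) exists.
* Spot-pair Wilcoxon inference accepts pseudo-replication (see above); treat
  its q-values as descriptive ranking at the sample sizes typical of spatial
  studies, or use the per-sample aggregation mode.
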