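---
title: "Spike-in-based decontamination of droplet scRNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in-based decontamination of droplet scRNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The contamination model

Droplet-based single-cell RNA-seq suspensions contain cell-free RNA released
by lysing cells. This ambient RNA is co-encapsulated with intact cells, so
every droplet's library is a mixture of the cell's own transcriptome and a
shared contaminating pool. spikeclean models the observed TPM profile of a
cell $c$ as

$$ x_c \;=\; (1 - f_c)\, t_c \;+\; f_c\, S, $$

where $t_c$ is the cell's true profile, $S$ is the sample-level
transcriptional signature of the contaminating pool (TPM scale, one vector
per sample), and $f_c \in [0, 1]$ is the cell-specific contamination
fraction. The pool is shared because it derives from the suspension, not
from the individual droplet; only its weight varies per cell. In tissues
where a few transcripts dominate — pancreatic islets, where the hormone
genes INS, GCG, SST and PPY can make up several percent of *all* reads —
this redistribution makes every cell look hormone-positive and inflates
apparent polyhormonality.

Neither $f_c$ nor $S$ is identifiable from contaminated cells alone. Both
become directly measurable when a well-characterized reference population of
*another species* is spiked into the suspension before droplet formation and
the data are aligned to a combined two-species reference:

* any read in a spike-in droplet that aligns to the sample genome is
  contamination, so $f_c$ is *measured* there as
  `reads_sample / (reads_sample + reads_spikein)` (`measure_fc()`);
* the sample-genome expression of spike-ins, compared to clean reference
  profiles sequenced in isolation, recovers $S$ (`estimate_signature()`).

### Species assignment

Barcodes are split by the log2 ratio of sample-genome to spike-in-genome
UMIs with an inclusive cutoff of ±2 (`assign_species()`); a pseudocount of 1
on both totals keeps one-sided barcodes finite without changing their
ordering. Barcodes between the cutoffs contain material from both species
(cross-species doublets or heavily mixed droplets) and are removed from all
estimation. Same-species spike-ins, which cannot be separated by genome, are
identified per cell by Pearson correlation > 0.9 to the mean clean reference
profile (`identify_same_species_spikeins()`); we apply the correlation rule
directly per cell rather than smoothing it over clusters, since graph
clustering is outside this package's scope.

### Signature estimation

Per spike-in, the observed sample-gene TPM vector is divided by $1 - f_c$,
the clean reference profile is subtracted, negative entries are set to zero,
and the remainder is rescaled to sum to $10^6$; these per-cell contamination
vectors are averaged and the mean renormalized, giving one signature per
sample. Rescaling happens at all three places where a vector must live on
the TPM scale (per-cell vectors before averaging, the final signature,
corrected cells); that is the only reading consistent with the TPM contract.
Samples with fewer than 20 usable spike-ins are refused rather than silently
estimated.

### Predicting f_c in ordinary cells

For cells without a cross-species readout, $f_c$ is predicted from the most
contaminating genes: the configured marker list is intersected with the top
100 genes of $S$ (`select_predictor_genes()`), each selected gene gets a
no-intercept linear slope $\beta_g$ regressing measured $f_c$ on TPM in the
spike-ins (`fit_fc_predictor()`), and a cell's prediction is the median over
genes of $\beta_g \cdot \mathrm{TPM}_g$, clipped to $[0, \mathrm{cap}]$
(`predict_fc()`). On the bundled simulator this intersection yields seven
genes (the four hormones plus IAPP, TTR, REG1A), mirroring the predictor
set that arises in real islet data.

One design point deserves emphasis: the predictor is fit on the
sample-species gene *rows of the combined-alignment TPM layer*, not on a
per-cell renormalized sample-genome slice. A cross-species spike-in's
sample-genome content is pure contamination, so renormalizing that slice to
$10^6$ per cell makes every contaminating gene's TPM independent of $f_c$
and destroys the regression signal; in the combined layer the denominator
includes the spike-in's own-species reads and hormone TPM scales linearly
with $f_c$. For ordinary cells the two layers agree (they carry essentially
no spike-in-genome reads), so the fitted slopes transfer.

The cap is a per-sample configuration value reflecting the contamination
range of the experiment (0.1 is the human-sample default, 0.2 the mouse
default). The bundled simulator draws $f_c \sim U(0.02, 0.2)$, so analyses
of simulated samples use the 0.2 cap; capping at 0.1 would systematically
under-correct the upper half of that range. Prediction quality is reported
by 3-fold cross-validation within spike-ins (`crossval_fc_predictor()`),
with folds shuffled under a caller-supplied seed.

### Correction

`correct_expression()` computes $x'_c = \max(0,\; x_c - f_c S)$ per cell and
rescales each non-empty column to $10^6$. Correction is deterministic,
non-negative, and conserves the TPM column sum to within $10^{-6}$ relative
— properties enforced by tests throughout the pipeline.

## Cell-type assignment

Clear representatives of beta, alpha, delta and gamma cells are assigned
when exactly one of INS, GCG, SST, PPY exceeds log(TPM) 7.5 (strict) on
*corrected* data; cells above the threshold for zero or several hormones are
`endocrine_unassigned` (a cell exceeding two hormone thresholds is not a
clear representative of either type). An analogous per-cell rule assigns
`acinar_like` by REG1A > 7.5 among still-unassigned cells, replacing the
cluster-level assignment that would otherwise require graph clustering.

A lasso-regularized multinomial logistic regression
(`glmnet::cv.glmnet`, alpha = 1, 5-fold cross-validated deviance) is trained
on these representatives, subsampled to at most 100 cells per (class,
sample) among control-condition cells of classes with more than 50 control
representatives. Every gene used for assignment — the four hormones *and*
REG1A when the acinar rule is active — is removed from the feature space, so
the classifier is marker-free by construction and cannot leak the defining
genes. Class probabilities are computed for all cells, but predictions
relabel only `endocrine_unassigned` cells; hormone-assigned labels are never
overwritten. Predictions use the penalty `lambda.1se`, the
cross-validation-conservative default.

### Doublet filters

Two filters flag suspected doublets:

1. **Probability ratio.** A singlet concentrates class probability on one
   class; a heterotypic doublet spreads it over its constituents. Cells with
   highest-to-second-highest probability ratio strictly below 3 are flagged.
   A second-highest probability of exactly zero gives an infinite ratio (the
   cell is kept).
2. **Detected genes.** Within each (cell type, sample) group of at least 30
   cells, the expected gene count is the mode of a Gaussian kernel-density
   estimate (Silverman's bandwidth, 512-point grid spanning the group range;
   in bimodal groups the higher-density peak wins); cells with strictly more
   than twice the expected count are flagged.

## Differential expression

`nb_test()` fits, per gene, a negative-binomial regression of raw counts on
the group indicator with a log-library-size offset. The gene-wise dispersion
is estimated by maximum likelihood on the pooled data under the null
(closed-form null means, `MASS::theta.ml`) and held fixed in both fits, so
the deviance difference is a 1-df likelihood-ratio statistic; this
stabilizes the test at small sample sizes. Genes are pre-filtered to
|ln fold change| ≥ 0.1; p-values are Benjamini–Hochberg adjusted
(`stats::p.adjust`), and a gene is significant when its linear-scale fold
change is at least 1.25 in either direction *and* the adjusted p-value is
below 0.05 (we read the 1.25-fold rule on the linear scale of mean
expression ratios; a flag-free pseudocount of 1 per-million guards the
ratio). Hormone genes are tested first on data including hormones; all other
genes are tested after removing the hormones and renormalizing
(`prepare_hormone_free()`), so hormone abundance cannot distort the library
composition of the second pass.

Marker genes per type are found by one-vs-rest AUC (> 0.75 after an
|mean log difference| ≥ 0.7 pre-filter), computed from the rank-sum
statistic with average ranks for ties. Cell identity scores are Spearman
correlations to mean control-condition type profiles over the marker union,
hormones excluded. Cross-species fold-change comparison joins the two
differential tables through an ortholog map restricted to strictly
one-to-one pairs and reports the Spearman correlation over genes significant
in either species. Hormone-positive fractions are inverse cumulative curves
(fraction of cells strictly above each grid level).

## The synthetic-data generator

`simulate_sample()` emulates one two-species droplet experiment with full
ground truth. Its defaults are the package's study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| cells per type | alpha 140, beta 140, delta 70, gamma 70, ductal 530 | endocrine minority sized so INS and GCG are each ~5% of all reads, matching observed hormone read shares in primary islet data |
| genes per species | 2000 | keeps the full suite fast while leaving a realistic long tail |
| hormone dominance | 0.4 | defining hormone's share of an endocrine cell's transcripts |
| marker blocks | 20 genes, share 0.15, anchors (TTR, IAPP, REG1A) at 40% of their block | non-hormone identity programs; anchors rank among top contaminants |
| marker overlap | 0.3 | type markers are enriched, not exclusive, across islet cell types |
| per-cell noise | log-normal, CV 0.3 | transcriptional heterogeneity within a type |
| spike-ins | 5% of cells | typical spike-in proportion |
| f_c | Uniform(0.02, 0.2) | observed per-cell contamination reaches ~20% |
| library size | log-normal, median 20000, sdlog 0.3 | droplet UMI depth |
| doublets | 5% of sample cells; merged pair thinned to 80% of pooled reads | a doublet contains two cells' RNA |

Counts are Multinomial($L$, $(1-f_c)\,p + f_c\,a$), where $p$ is the cell's
(noised) program and $a$ the ambient pool — the library-size-weighted mean
of the clean sample-species programs, i.e. lysing cells contribute in
proportion to their RNA content. Contamination acts pre-sampling as a
mixture of proportions, which reproduces the read-fraction arithmetic of
measured $f_c$ exactly. Spike-in cells use the other species' program, so
their sample-genome reads arise only from ambient material. Ambient hormone
shares can be pinned (`ambient_hormone_share`) to emulate reported
read-share figures. Everything is deterministic given the seed.

What the generator does *not* emulate: sequencing error, UMI collisions,
batch effects, index switching, empty droplets, and — importantly — the
sparse gene-detection regime of real data. With 2000 genes and a median
library of 20000, a typical cell detects ~90% of the gene space, so a
doublet cannot reach twice the modal detected-gene count and the
detected-genes doublet filter, while verified on its own fixtures, is inert
at simulator scale. Passing tests on this generator therefore demonstrate
the estimators' correctness and calibration under the stated mixture model,
not their performance on any particular real tissue.

## Known limitations

* **Doublet probability-ratio threshold.** With `cv.glmnet`'s
  `lambda.1se` penalty, log-probability gaps are compressed to a
  self-limited scale (singlet median gap ≈ 4 nats on simulated data
  regardless of true class separability). The fixed 3-fold ratio then falls
  inside the doublet gap distribution: on the default simulation the
  combined filters remove only ~20–40% of heterotypic doublets (at < 1%
  singlet loss), although the probability gaps themselves separate doublets
  from singlets well (97% vs 9% at a ~20-fold ratio). The information is
  present; the fixed threshold does not transfer to this desk-scale
  geometry. We deliberately did not recalibrate probabilities or move the
  threshold.
* **Acinar-like assignment** is a per-cell marker rule, not a cluster
  label; cells co-expressing REG1A through residual contamination are
  protected only by the correction step that precedes assignment.
* **Signature estimation** assumes the clean reference matches the spike-in
  lot; systematic reference mismatch is absorbed into the signature.
* The NB dispersion scheme is documented (pooled-null ML, fixed in both
  fits) but not guaranteed numerically identical to any other package's
  negative-binomial test.

## Problem sizes used by the test suite

Unit tests run on reduced fixtures (~200 cells, 400–500 genes, library
5000). The acceptance-style checks use the full default conditions: 950
sample cells + 300 spike-ins at library 20000 for contamination recovery and
correction; 4 × 100 endocrine cells for the classifier; 2000 null genes at
n = 100 per group and 200 single-gene replicates for the NB test. These
sizes were chosen so the whole suite completes in a few minutes on one core
while keeping every Monte-Carlo margin comfortable.
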