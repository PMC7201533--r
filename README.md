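# spikeclean

Removal of cell-free-RNA contamination from droplet single-cell RNA-seq
using cross-species spike-in reference cells, with downstream marker-free
cell-type assignment, doublet filtering, and cell-type-specific differential
expression. Written for transcriptomics analysts working with tissues —
such as pancreatic islets — where a handful of highly expressed transcripts
dominate the ambient pool and make every droplet look like it expresses
them.

## The method

Ambient RNA from lysing cells is co-encapsulated with intact cells, so the
observed TPM profile of cell *c* is a mixture

    x_c = (1 − f_c) · t_c + f_c · S

of the cell's true profile `t_c` and a sample-wide contamination signature
`S`, weighted by a per-cell contamination fraction `f_c`. Both unknowns are
measurable when reference cells of another species are spiked into the
suspension (~5% of cells) and reads are aligned to a combined two-species
genome:

1. **Measure** `f_c` in spike-ins as the fraction of their reads aligning
   to the sample genome (`measure_fc()`).
2. **Estimate** `S` per sample by dividing spike-in sample-genome TPM by
   `1 − f_c`, subtracting the clean reference profile, clipping negatives,
   rescaling to TPM, and averaging (`estimate_signature()`).
3. **Predict** `f_c` for all other cells as the capped median of per-gene
   no-intercept linear predictions from the most contaminating marker genes
   (`select_predictor_genes()`, `fit_fc_predictor()`, `predict_fc()`).
4. **Correct** every cell: `x' = max(0, x − f_c·S)`, renormalized to TPM
   (`correct_expression()`).

Downstream, corrected cells are typed by hormone thresholds (log TPM > 7.5)
plus a lasso multinomial classifier trained without the assignment genes
(`assign_by_hormone()`, `train_classifier()`, `predict_celltype()`),
doublets are flagged by class-probability ratio and detected-gene count,
and condition contrasts use a per-gene negative-binomial likelihood-ratio
test with BH correction and a 1.25-fold significance rule (`nb_test()`).
A fully ground-truthed two-species simulator (`sim_config()`,
`simulate_sample()`) makes every step testable without any download.

## Worked example

```r
library(spikeclean)

# a two-species islet-like sample: 950 cells, 300 mouse spike-ins,
# contamination f_c ~ U(0.02, 0.2)
sim <- simulate_sample(sim_config(n_spikeins = 300, seed = 1))

calls <- assign_species(sim$cm_combined)      # hs:/mm: read ratio, cutoff 2
fc    <- measure_fc(calls)                    # measured f_c per spike-in
median(fc$f_c)
#> [1] 0.109143

em    <- tpm_normalize(sim$cm_combined)
hs    <- sim$programs$genes_sample
spike <- intersect(colnames(em$values), fc$barcode)
em_sp <- expression_matrix(em$values[hs, spike], "tpm", check = FALSE)
sig   <- estimate_signature(em_sp, fc, setNames(numeric(length(hs)), hs))
sig
#> ContaminationSignature 'sample' over 2000 genes; top genes: hs:REG1A (64841),
#>   hs:GCG (58022), hs:INS (57256), hs:PPY (30031), hs:SST (28541)

select_predictor_genes(sig, sim$programs$markers)
#> [1] "hs:REG1A" "hs:GCG"   "hs:INS"   "hs:PPY"   "hs:SST"   "hs:IAPP"
#> [7] "hs:TTR"
```

The signature is dominated by the hormone and acinar transcripts that
dominate the suspension — exactly the genes whose apparent ubiquity is the
artifact being removed. The intersection with the configured marker list
gives the seven predictor genes; fitting them and correcting the sample
drops the hormone TPM planted in non-endocrine cells by ~99% and raises
every spike-in's correlation to its clean reference.

The full pipeline (simulate → ingest → species → decontam → celltype → de)
runs as one call:

```r
res <- run_pipeline(run_config(sim = sim_config(seed = 1), fc_cap = 0.2,
                               seed = 1))
res$report$n_stages
#> [1] 6
```

or from a shell via the thin wrapper `scripts/spikeclean.R`.

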