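# haemodyn

Single-cell analysis of haematopoietic lineage dynamics.

`haemodyn` re-implements, as a tested and reusable R pipeline, the
computational workflow of a single-cell RNA-seq study of blood
differentiation along a branching trajectory: a multipotent
stem/progenitor (HSPC) root that resolves into erythroid, monocyte,
neutrophil and thrombocyte lineages. It is aimed at computational
biologists who want each bespoke step of such a study — quality control
with an erythroid rescue, spike-in-anchored variable-gene calling,
censored-Gaussian differential testing along pseudotime, a neural lineage
classifier with a stemness index, and duplication/conservation analysis —
as an explicit, unit-tested function rather than a one-off script.

## What the package computes

* **Cell QC with a globin rescue** — a cell fails when it has fewer than
  1000 expressed genes (TPM > 1), or more than 60% spike-in (ERCC) or
  mitochondrial content; a failing cell is rescued when it expresses both
  adult globins above thresholds (ba1 > 40,000 TPM, hbaa1 > 9,000 TPM),
  because erythroid cells legitimately express few genes.
* **CPM normalisation and gene filtering** — counts per million per cell;
  genes kept when CPM > 1 in at least 1% of cells.
* **Technical noise and HVGs** — the spike-in squared coefficient of
  variation is fitted as CV²(μ) = a₁/μ + a₀; a gene is highly variable
  when its CV² significantly exceeds the technical CV² at its mean plus a
  stated biological variation level (χ² test, BH q < 0.1).
* **Tobit differential and dynamic tests** — expression y = log10(CPM+1)
  is modelled as a left-censored Gaussian (zeros censored at c = 0) and
  nested models are compared by likelihood ratio:
  full `~ state` vs reduced `~ 1` for state markers, and a natural cubic
  spline of pseudotime (df = 3) vs `~ 1` for pseudotime-dependent genes;
  significance requires P < 0.01, BH q < 0.1 and expression in more than
  50% of tested cells. Significant trends are clustered (Euclidean,
  ward.D2) with the number of clusters chosen by silhouette score, and
  average trends are summarised by `y ~ poly(x, 2)` fits with a 95%
  standard-error band.
* **Lineage classifier and stemness** — a feed-forward network
  (100 and 50 rectified-linear hidden nodes, L2 weight decay λ = 0.001,
  Gaussian dropout 0.8 between the hidden layers, softmax output,
  categorical cross-entropy, 20% validation split) maps a cell's
  z-scored expression vector to lineage probabilities p_i. The stemness
  index is the Kullback–Leibler divergence
  S_i = Σ_j p_ij log(p_ij / p̄_j), where p̄ is the average probability
  vector; cells with S_i below a threshold (default 0.05) are called
  stem-like.
* **Ribosomal programmes** — average log10 expression profiles per cell
  type, per-gene CV across cell types, high/low expression tiers, and
  pairwise Pearson correlations of cytosolic-ribosomal profiles.
* **Conservation and divergence** — cell-type gene sets from the DE
  results, ortholog-conservation percentages against a gene-by-species
  table, splitting of paralogs into exclusively pre- vs post-speciation
  duplications (by duplication-node taxon), and classification of
  post-speciation duplicates as expression-conserved vs diverged.

Everything runs on a bundled synthetic-data generator
(`simulate_dataset()`) whose mean functions are analytic, so every trend
or recovery claim is testable without external data.

## Worked example

```r
library(haemodyn)

d   <- simulate_dataset(sim_params(seed = 11))
tpm <- counts_to_tpm(d$counts)
qc  <- apply_qc(tpm, d$annotation, compute_qc_metrics(tpm, d$annotation),
                analysis_config())
table(qc$report$qc_pass)
#> FALSE  TRUE
#>    25   475

cpm  <- cpm_normalize(em_subset(d$counts, cells = which(qc$report$qc_pass)))
filt <- filter_genes(cpm, analysis_config(), d$annotation)
filt
#> ExpressionMatrix: 475 cells x 1645 genes [CPM]

fit <- fit_technical_noise(filt, d$annotation)
fit
#> NoiseFit: CV2 = 41.24/mu + 0.1527 (fit on 92 spike-ins, 475 cells)

meta <- d$metadata[match(cell_ids(filt), d$metadata$cell_id), ]
logm <- log10_cpm1(filt)
committed <- meta$branch_label != "HSPC"
model <- train_classifier(logm$values[committed, ],
                          meta$branch_label[committed],
                          classifier_spec(seed = 11))
model
#> haem_classifier: 1645 genes -> 100/50 -> 4 classes (erythroid, monocyte,
#>   neutrophil, thrombocyte)
#>   best epoch 60: val_loss 0.2868, val_accuracy 1.000

stem <- call_stem_cells(stemness_scores(predict_probabilities(model, logm)),
                        analysis_config())
stem
#> StemnessResult: 475 cells, mean S = 1.1811
#>   7 stem calls at tau = 0.05 (fixed mode)
```

Here 25 of 500 simulated cells are the planted QC violators (the five
globin-rescue erythroid cells pass), the noise fit recovers the spike-in
counting-noise slope, the classifier separates the four committed
lineages perfectly on held-out cells, and multipotent root cells receive
markedly lower stemness scores than committed ones (mean 0.36 vs 1.39 on
this seed), which is what the stem-cell call thresholds.

`run_all()` chains all eleven stages (simulate → qc → normalize → filter
→ hvg → train → predict → stemness → dynamics → ribosome → conserve),
writes per-stage artefacts plus a manifest with md5 checksums, and is
bit-reproducible under a fixed seed.

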