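---
title: "Models and methods behind haemodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haemodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haemodyn)
```

`haemodyn` packages the bespoke computations of a single-cell study of
branching blood differentiation as explicit, tested functions. This
vignette describes each model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the bundled
synthetic data can and cannot establish.

## Quality control with an erythroid rescue

QC operates on the TPM matrix. A cell fails when any of three strict
rules fires: fewer than 1000 expressed genes (TPM > 1), more than 60%
of total TPM from ERCC spike-ins, or more than 60% from mitochondrially
encoded genes. "Fewer than" and "more than" are read literally, so a
cell sitting exactly on a boundary passes. Erythroid cells legitimately
express few genes while being dominated by globins, so a failing cell is
rescued when it expresses both ba1 (> 40,000 TPM) and hbaa1
(> 9,000 TPM), again strictly. If the rescue genes are missing from the
matrix, the rescue is disabled with a warning rather than an error, so
the pipeline still runs on data without globin annotations.

Two interpretation choices are deliberate and exposed: spike-ins are
excluded from the expressed-gene count (they are not part of the cell's
transcriptome) but included in the denominator of the ERCC and
mitochondrial fractions; and all thresholds live in `analysis_config()`
rather than in function bodies.

Normalisation for analysis is counts per million: each cell's counts
divided by its total, times 1e6, so every row sums to exactly 1e6. QC
uses TPM and analysis uses CPM — the two-unit workflow of the original
protocol. `cpm_normalize()` accepts user-supplied size factors as a hook
for deconvolution-based normalisation, which is otherwise out of scope.
Genes are retained when they reach CPM > 1 in at least 1% of cells;
"at least 1%" is rounded up (`ceiling`), so with 200 cells a gene needs
2 positive cells. Spike-ins are exempt from the filter because the noise
fit needs them regardless of prevalence.

## Technical noise and highly variable genes

Spike-ins are present at fixed concentrations, so their CV² across
cells is technical. On the per-million scale counting noise gives
CV²(μ) ≈ a₁/μ with a₁ the ratio of 1e6 to the sequencing depth, plus a
mean-independent floor a₀. The fit is least squares of spike CV² on
1/μ with weights iterated as 1/fitted² (a gamma-type variance
assumption appropriate for a squared CV), which keeps high-expression
spike-ins from being drowned out by the noisy low-expression ones.

A gene is called highly variable when its CV² significantly exceeds the
technical CV² at its mean plus a stated biological variation level
(`bio_cv2_threshold`, default 0.25; the 0.05/0.25/0.95 ladder reproduces
the usual sensitivity analysis). Under the null CV²_true = tech + bio,
(n−1)·CV²_obs/CV²_null is approximately χ²(n−1); one-sided p-values are
BH-adjusted and q < 0.1 selects. Because the null grows with the
threshold, the selected set shrinks monotonically as the threshold
rises — a property the tests assert. The χ² approximation treats cells
as independent and the mean as known; both are standard simplifications
at these cell numbers.

## Tobit differential and dynamic expression

Expression y = log10(CPM+1) is modelled as a left-censored Gaussian:
a latent level xβ + σε observed only above a detection limit c, with
zeros censored. The default c = 0 makes exactly the zeros the censored
class; c is configurable because detection limits differ between
quantifiers. The log-likelihood is

ℓ = Σ_{y>c} log φ((y − xβ)/σ)/σ + Σ_{y≤c} log Φ((c − xβ)/σ).

Maximisation is BFGS in (β, log σ) with the analytic gradient
(convergence tolerance 1e-10, 500 iterations). The state test compares
`~ state` against `~ 1` with χ²(#states − 1); the dynamic test compares
a natural cubic spline basis of pseudotime (df = 3, the default of the
spline smoother used by trajectory frameworks) against `~ 1` with
χ²(3). The full model is additionally started from the reduced
solution, so its likelihood can never fall below the reduced one and
the LRT statistic is non-negative by construction. Genes with no
uncensored variation get statistic 0 and p = 1; non-convergent genes
are reported NA and excluded from the BH adjustment. Significance
requires p < 0.01, BH q < 0.1 and expression above c in more than 50%
of the tested cells; the expressed fraction is evaluated over the cell
subset entering each test (per state-comparison or per branch), the
closest reading of the published rule.

Calibration is checked against data drawn from the censored-Gaussian
model itself (latent normal, censored at 0): calibration concerns the
null distribution of the statistic under the model, and the χ²
reference is exact only there. On 1000 null genes the fraction with
p < 0.01 stays within [0.003, 0.025], and a log10 four-fold shift in
one of five states (100 cells each) is detected with power above 0.9.

Significant genes' trends are summarised by least-squares spline fits
evaluated on a 100-point grid spanning the branch's observed pseudotime
range, z-scored per gene, and clustered hierarchically (Euclidean
distance, ward.D2). The cluster number k in 2..6 maximises the mean
silhouette width; when even the best mean silhouette is below 0.25 the
genes are treated as a single trend — this guard handles the degenerate
all-identical case where silhouette rankings are meaningless. Average
trends per cluster are fitted with `y ~ poly(x, 2)` and a pointwise
95% standard-error band from the fit covariance.

## The lineage classifier

The classifier is a feed-forward network mapping a cell's z-scored
expression vector to softmax probabilities over the four committed
lineages: hidden layers of 100 and 50 rectified-linear nodes, L2 weight
decay λ = 0.001 on all weight matrices, and Gaussian dropout of rate
0.8 between the hidden layers. Gaussian dropout with rate r multiplies
activations by N(1, r/(1−r)) noise during training, so rate 0.8 means
noise sd 2; the alternative "keep-probability 0.8" reading (sd 0.5)
exists, and the chosen interpretation follows the convention of the
deep-learning framework the architecture is stated in. Dropout is
disabled at prediction, making prediction deterministic.

Standardisation uses the population standard deviation (divide by n),
computed on the training split only and applied unchanged at
validation and prediction time; constant genes map to zero, and genes
missing at prediction are imputed as zero after standardisation (the
training mean) with a warning. The optimiser, learning rate, batch
size and epoch budget are not part of the published architecture, so
the package fixes a standard choice — Adam at 1e-3, minibatch 64, up to
60 epochs with early stopping (patience 8) on the loss of a stratified
20% validation split — and records the full per-epoch history in the
returned model. All randomness (split, initialisation, shuffling,
dropout noise) derives from one seed, so training is bit-reproducible.

## The stemness index

Given probabilities p_i and the average probability vector p̄ (column
means by default), the stemness index is the KL divergence
S_i = Σ_j p_ij log(p_ij/p̄_j) with 0·log 0 = 0. Committed cells
concentrate mass on one class and score high; cells resembling the
population mixture score near zero, so *low* values flag stem-like
cells. The natural logarithm is the default; because a fixed call
threshold is base-dependent, the base is exposed. Tiny negative values
from floating-point cancellation are clamped to zero; a reference with
a zero entry where cells have positive probability is rejected
(undefined divergence).

The published call rule ("3 sigma over the mean stemness value
(0.05)") is ambiguous given that lower scores are more stem-like, so
the call is configurable rather than guessed: fixed mode thresholds at
τ = 0.05 (the default), data mode at τ = max(0, mean(S) − 3·sd(S)).
Both are recorded in the result. Calls use S < τ strictly.

## Ribosomal programmes

Cell-type average profiles are means of log10(CPM+1) per gene within
each type. The per-gene CV across cell types is sd/mean with the
sample (n−1) standard deviation, computed on the averaged log10
profiles — the order of operations stated in the source workflow; since
linear-scale CV is a defensible alternative, the profile unit is
explicit in the API. Ribosomal genes are tiered "high" when expressed
(CPM > 1) in at least 50% of cells (boundary inclusive, threshold
configurable); on the synthetic data this split recovers the
cytosolic (high, decaying in pseudotime) versus mitochondrial (low,
trend-free) programmes. Pairwise Pearson correlations of the
cytosolic-ribosomal average profiles quantify how strongly the
programme is shared between cell types.

## Conservation and divergence

Cell-type gene sets take the significant DE genes that are
protein-coding, expressed in more than 50% of the type's cells
(strict), and whose mean log10(CPM+1) in the type exceeds a score
floor. The published floor ("more than mean log10 counts") is read as:
above the global mean of per-gene average log10 expression over all
candidate genes; a fixed floor can be configured instead. The non-DE
background set takes protein-coding genes expressed in more than 1% of
cells with global average log10 expression above 0.10 that are not
significant, so DE and background sets are disjoint by construction.

Ortholog conservation of a set is the percentage of its genes with an
ortholog present in *every* named species. Paralogs are split by the
taxon of their duplication node into pre-speciation (Euteleostomi,
Bilateria, Chordata, Vertebrata, Opisthokonta) and post-speciation
(Neopterygii, Otophysa, Clupeocephala, Danio rerio) groups; genes with
duplications in both epochs are removed from both. A post-speciation
duplicate is expression-conserved when every expressed paralog (a
paralog with CPM > 1 in more than 10% of some branch's cells) is
expressed in exactly the same branch set, diverged when at least one
expressed paralog differs, and unclassifiable when no paralog passes
the expression rule. The published rule covers only the
single-cell-type case; the package extends it so that any asymmetry in
branch sets counts as divergence, the stricter and more conservative
reading.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: a multipotent HSPC root (pseudotime 0–0.3) and four committed
branches (0.3–1); per-branch lineage markers rising logistically
(midpoint 0.5, steepness 0.12, default eight-fold rise) within their
own branch and flat at a low level elsewhere; cytosolic ribosomal
genes decaying exponentially (rate 1.5 over the unit pseudotime range)
in every lineage; low, trend-free mitochondrial-ribosomal genes; flat
housekeeping and null genes; a small mitochondrially encoded gene set
for the QC fraction; and 92 spike-ins from a fixed log-uniform
concentration pool independent of cell state. Endogenous counts are
negative binomial (dispersion 0.3) around the analytic means scaled by
a log-normal library-size factor (sd 0.3 on the log scale); spike-ins
are Poisson, carrying technical noise only. Root cells express a
convex (near-uniform Dirichlet) mixture of the branch marker
centroids, planting a positive set for the stemness analysis. Five
percent of cells are planted QC violators (too few genes, excess
spike-in content, or excess mitochondrial content, far from the
thresholds so the QC confusion matrix is exact), and five percent of
erythroid cells are globin-rescue cases (endogenous expression scaled
down below 1000 expressed genes, globins set high enough that their
TPM clears the rescue thresholds with large margin). The logistic and
exponential trend shapes are smooth monotone choices matching the
rising/falling two-trend picture without claiming any particular
published functional form; the mitochondrial-ribosomal scale is set
low enough (log-normal around 0.25 counts) that the programme tiers
"low" under the 50% rule, as its description requires. All trend
claims are asserted against the analytic mean functions
(`expected_mean_profile()`), independent of sampling.

What the generator does *not* emulate: batch and plate effects,
cell-cycle structure, doublets, gene–gene correlation beyond the
shared programmes, realistic gene-length variation (all genes share an
effective length, so the TPM matrix is the per-million count scaling),
and continuous branching geometry (branch labels and pseudotime are
ground truth, not inferred). Passing tests therefore demonstrate that
the implementations compute what they claim under the assumed model —
not that the thresholds are optimal for any particular real dataset.

## Problem sizes and reproducibility

The bundled walkthrough (`run_all()`) uses the default 500-cell,
~1600-gene conditions; its Tobit stages run on the 300
highest-expressed endogenous genes (`dyn_genes_max`), a cap chosen to
keep the demonstration desk-sized while exercising every code path —
the per-stage functions impose no cap. Calibration checks use 1000
null genes at 500 cells; the noise benchmark uses 5000 cells; the
classifier benchmark uses 800 cells by 2000 genes. Every stochastic
operation takes an explicit seed, and the pipeline writes md5 checksums
of its artefacts so bit-reproducibility is checkable.

## Known limitations

* The χ² reference for the LRT and the CV² test are asymptotic; at few
  cells per state the null calibration degrades.
* The Tobit model assumes a single censoring threshold shared by all
  cells; cell-specific detection limits are not modelled.
* The silhouette criterion cannot choose k = 1; the 0.25 floor is a
  pragmatic guard, not an inferential test.
* The classifier trains on whatever gene set survives filtering; no
  feature selection is performed, matching the stated
  train-on-all-genes contract.
* Trajectory reconstruction itself (branch assignment, pseudotime
  inference) is out of scope: the pipeline consumes labels, here
  supplied by the generator's ground truth.
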