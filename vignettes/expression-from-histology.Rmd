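---
title: "Predicting spot-level gene expression from H&E histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spot-level gene expression from H&E histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(histex)
```

This vignette is the methods account of histex: the models and procedures
it implements, the assumptions behind them, the parameters that matter, and
the design decisions taken where several defensible options existed.

## The task and its assumptions

Spatial transcriptomics (ST) pairs a gene-count vector with a pixel
location on an H&E image for every array spot.  histex learns a mapping
from a square image patch centered on a spot to that spot's log-scale
expression vector.  The approach rests on three assumptions:

* **Locality** — a spot's expression is largely explained by the tissue
  within its immediate neighborhood, so a patch (224 px at 20×, roughly
  the spot pitch) is an adequate predictor input.
* **Stain-invariance after normalization** — H&E color varies between labs
  and batches; after mapping images to a common stain basis, pixel values
  are comparable across sections and patients.
* **Log-scale homoscedasticity** — counts are heavily right-skewed;
  `ln(1 + x)` stabilizes the variance enough for a squared-error loss to
  be sensible.

## Stain normalization

Stain mixing is approximately linear in optical density (Beer–Lambert):
`OD = -ln(I / I0)` with `I0 = 255`, and `OD ≈ C·S` where `S` is a 2×3
matrix of unit-norm stain color vectors (hematoxylin, eosin) and `C ≥ 0`
the per-pixel concentrations.  `estimate_stain_profile()` solves the
sparse non-negative factorization over tissue pixels (CIELAB luminosity
< 0.8) by alternating:

* vectorised coordinate descent on `C` with an L1 penalty
  (`sparsity_weight = 0.1`) — each of the two coordinates has a
  closed-form non-negative update;
* a least-squares update of `S`, projected to the non-negative orthant and
  row-normalized.

Numerical choices: intensities are clamped at 1 before the log so OD stays
finite; the iteration starts from the standard literature H&E OD
directions (a deterministic, well-posed start), caps at 200 alternations
with tolerance 1e-4 on the stain matrix, and subsamples at most 50,000
tissue pixels (seeded) — ample for a 2×3 factor.  Two tie-breaks are fixed
by convention: row 1 of every profile is hematoxylin, identified as the
stain with the larger red-channel OD (hematoxylin absorbs red strongly,
eosin barely); and if one stain collapses to zero on a single-stain image,
its row keeps the previous unit-norm direction and the profile is flagged
low-confidence rather than returning a degenerate matrix.

Normalization rescales concentrations channel-wise by the ratio of
99th-percentile concentrations (`reference / source`) and re-composes
through the reference stain matrix.  Background pixels have near-zero OD
and therefore stay white.  The concentration percentile (99) trades
robustness to outlier pixels against sensitivity to genuinely dense
staining.  `standardize_luminosity()` divides CIELAB L by its 95th
percentile, clipping into range — an idempotent white-point correction.
The reference profile is a user choice (one designated image per dataset);
no universal reference exists and the choice is exposed rather than
hidden.

## Preprocessing

The pipeline order is fixed and tested: pooled gene filter → per-spot
count filter → patch extraction → (log transform, gene selection).

* **Gene filter**: genes with zero mean expression pooled across all spots
  of all samples are dropped (exactly the all-zero columns).
* **Spot filter**: spots with fewer than `min_total = 1000` summed counts
  are dropped; the bound is inclusive ("at least 1000").
* **Patches**: the half-open box
  `[y − ⌊s/2⌋, y − ⌊s/2⌋ + s) × [x − ⌊s/2⌋, x − ⌊s/2⌋ + s)` centered on
  the spot, with 0-based coordinates, x = column, y = row.  One documented
  convention prevents off-by-one drift; nothing in the data formats forces
  a particular one.  Boundary spots are skipped, not padded — padding
  would fabricate tissue.  A patch is excluded when its fraction of white
  pixels (all three channels ≥ 220) is strictly greater than 0.5; a patch
  at exactly 50% is retained.  "White" needed an operational definition;
  220 on all channels is configurable.
* **Selection**: the main head predicts the `K = 250` genes with highest
  mean expression across retained spots, ties broken lexicographically so
  the selection is deterministic.  Ranking uses raw counts by default —
  the log transform is monotone per gene but reorders means across genes;
  ranking on log counts is available (`rank_on = "log"`).  The white-pixel
  rule is applied to the (stain-normalized) images as given to
  `preprocess_dataset()`; normalizing first keeps the whiteness threshold
  comparable across sections.

Patch standardization subtracts per-channel means and divides by
per-channel standard deviations.  In training these statistics come from
the fold's training patches only (no information leaks from validation or
test); a per-patch mode exists for exploratory use.

## Model and loss

`build_model()` assembles a backbone feature extractor with two linear
heads on the same penultimate features: the main head (K genes) and an
auxiliary head — a single fully connected layer — for the remaining genes.
The training objective is

\[ \mathcal{L} = \mathcal{L}_{\text{main}} + \lambda\,\mathcal{L}_{\text{aux}}, \qquad \lambda = 40. \]

The auxiliary task forces the shared features to explain the full
transcriptome rather than just the top panel, acting as a regularizer; at
`lambda = 0` the auxiliary head receives exactly zero gradient (a tested
contract).  The per-head loss is mean squared error on `ln(1 + count)`
targets; a smooth-L1 (Huber) option is provided for robustness to outlier
spots.  Squared error is the natural choice for continuous log-expression
regression and is what the MAE/RMSE/PCC evaluation measures; a
cross-entropy-style objective would require discretising expression into
bins, which this package deliberately does not do.

Weights are randomly initialised (He scaling; head weights at sd 0.01) —
no pretraining.  Head biases start at the per-gene training means so early
epochs fit structure rather than offsets; this is equivalent to centering
the targets and speeds convergence without changing the optimum.

The network engine is implemented in-package in matrix form (im2col
convolutions, explicit backward passes, SGD with momentum and L2 weight
decay).  Every layer's gradient is verified against central finite
differences in the test suite.  `tiny_cnn` — three stride-reducing
conv/ReLU blocks and global average pooling, 64 features — is the
desk-scale backbone used in all trained examples.  The standard family
names (`resnet101`, `inception_v3`, `efficientnet_b0`–`b5`, `vit_b16`,
`vit_b32`) construct compact presets with the family's characteristic
topology (residual stages in the 3-4-23-3 layout, parallel-branch
inception blocks, compound depth/width scaling at the canonical 1.2/1.1
coefficients, patch-embedding transformer encoders with multi-head
self-attention); they are CPU-sized re-expressions for experimentation,
not ImageNet-scale replicas, and their construction and forward/backward
passes are smoke- and gradient-tested.

## Training protocol

Splits are by patient, never by spot or section: one patient is held out
entirely as the test set, and the remaining patients are partitioned into
5 cross-validation folds (sizes differing by at most 1; each non-test
patient validates exactly once).  An id audit inside `run_experiment()`
asserts that no test-patient spot reaches any training or validation
loader.

Defaults in `train_config()`: batch size 32, up to 200 epochs, SGD at
lr 0.001 with momentum 0.9 and weight decay 1e-4, reduce-on-plateau
scheduling (factor 0.1, patience 10) and early stopping (patience 20),
both driven by the validation *combined* loss so the auxiliary head also
governs regularization decisions.  Momentum, weight decay and the
scheduler/stopping patiences are exposed configuration — reasonable
middle-of-the-road values, not tuned constants.  Gradients are cleared at
every step; augmentation (independent horizontal flip, vertical flip and
90° rotation, p = 0.5 each — the orientation-invariance group of
histology) applies to training batches only.  The best-validation-loss
parameter state is checkpointed and restored at the end, so the returned
model is never worse than the best epoch observed.  A NaN loss aborts
with the epoch and batch in the message rather than training onward.

All randomness (weight init, shuffling, augmentation, subsampling) derives
from explicit seeds; with equal seeds, two runs produce bit-identical
prediction tables (a tested contract, assuming single-threaded BLAS).

## Evaluation

Per gene: MAE and RMSE pooled over all (fold model, test spot) pairs, and
the Pearson correlation computed per fold model across the test patient's
spots, aggregated as the **median across the 5 fold models**.  The
aggregation unit was a genuine design fork — median over fold models
versus median over the test patient's sections; fold models are the
default because every fold model scores the *whole* test patient (sections
can be few and small), and `--group-by section` remains available.
Correlation classes use a strict upper boundary: strong means PCC
strictly greater than 0.50, so exactly 0.5 is medium.  Genes with constant
truth or prediction have undefined correlation; they are reported as
missing and excluded from medians rather than coerced to zero, which would
silently deflate (or inflate) class counts.  `aMAE`/`aRMSE` average the
per-gene, spot-pooled errors over genes — not over genes × units — so
each gene contributes once regardless of fold count.

## The synthetic generator

`generate_dataset()` emulates the structure of a multi-patient ST cohort
without any real data:

* an H&E-like image composed in OD space from two smooth latent fields —
  eosin intensity and nuclei density (discs sampled from the density) —
  inside a blobby tissue mask on a white background;
* spots on a jittered regular grid (jitter ≤ 10% of pitch), ids in the
  array's `row x col` convention;
* counts for **signal genes** drawn Poisson with rate
  `base_j · ((1 − θ) + θ · u_j(s))`, where
  `u_j(s) = softplus(1 + w_j·f(s)) / mean` and `f(s)` are the latent
  fields averaged over the spot's patch box; `θ = signal_strength`
  interpolates between flat rates (θ = 0, pure counting noise) and fully
  image-driven rates (θ = 1).  **Noise genes** are Poisson with
  spot-independent rates.  Negative binomial counts with configurable
  dispersion are available, since real ST counts are overdispersed;
  Poisson is the analytically transparent default.
* signal genes are generated as the *high-expression* panel (65% of the
  per-spot total across 20 genes, against 35% across 50 noise genes, with
  moderate within-group spread), mirroring the study design in which the
  main head predicts the top-expressed genes — so mean-expression
  selection deterministically recovers the signal panel.

The reference desk-scale study used throughout the tests and the
acceptance script: 6 patients × 1 section × 200 spots, 352-px images,
64-px patches, 20 signal + 50 noise genes, `signal_strength = 0.9`,
`count_scale = 2000` (every spot clears the 1000-count filter), tiny_cnn +
auxiliary head at λ = 40, 25-epoch training with scheduler patience 4 and
early-stopping patience 8, 5-fold CV on 5 patients and one held-out
patient.  These sizes are the package's reference configuration for a
single-CPU workflow; at them, the held-out-patient median PCC exceeds 0.5
for nearly all signal genes while noise genes stay near zero.

With `signal_strength = 1` and noise-free rates, a linear readout of the
latent features reproduces the per-gene rates with PCC > 0.99 (softplus
operates in its near-linear range) — the ceiling against which the trained
model is compared.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: nuclei morphology and texture (discs, not
cells), batch-level stain variation between synthetic patients, section
thickness and focus artifacts, overdispersion (by default), zero-inflation,
gene–gene correlation structure beyond the two shared latent fields, and
any biological pathway structure.  Results on the synthetic study validate
the machinery (shapes, splits, optimization, metrics), not clinical
performance.

## File formats and fixtures

Sections are plain rasters (PNG/TIFF; JPEG via EBImage) with TSV/CSV spot
tables and counts matrices — dialects are auto-detected since the field's
coordinate files are schema-less text.  The filtered cohort is persisted
as a spot-bundle archive: a standard ZIP of named TSV arrays (`count`,
`pixel`, `patient`, `index`), written by a small stored-ZIP writer in base
R and readable by any unzip tool; a directory of per-spot archives is also
accepted on read (index order restores the dataset).  Unmapped Ensembl
ids keep the original id as their symbol and are counted, never dropped —
dropping would silently shrink the transcriptome.

## Known limitations

* The matrix-form engine is single-threaded-BLAS fast for desk-scale
  studies, not for 224-px patches across tens of thousands of spots; the
  architecture presets are compact stand-ins at that scale.
* Stain estimation assumes exactly two stains; immunohistochemistry or
  heavy artifacts violate the model.
* The reduce-on-plateau/early-stopping patiences interact: with very small
  patience both can trigger on noise in small validation folds.
* Median-PCC aggregation across 5 fold models is robust but coarse; with
  fewer folds the median is dominated by single models.
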