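---
title: "Pathway-panel image classification of platelet RNA-seq profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-panel image classification of platelet RNA-seq profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platimg)
```

## The problem

Blood platelets take up and splice RNA in response to signals from a growing
tumor; the transcriptome of these "tumor-educated" platelets (TEPs) carries a
diagnostic signal that can be read from a standard blood draw. platimg
implements a classifier for such profiles that departs from the usual
gene-vector machine-learning recipe in one key way: each sample's expression
vector is first rearranged into a two-dimensional image whose rows are
curated pathways (cancer, signaling and metabolism blocks, in that order)
and whose pixels are the member genes of each pathway, intensity-coded by
normalized expression. A small convolutional network then classifies the
images. Because a gene that participates in several pathways paints several
pixels, the image encodes pathway membership — and the convolution sees
local co-expression structure within a pathway — rather than treating genes
as exchangeable coordinates.

## Preprocessing model

The pipeline starts from a gene-level count matrix. Three standard steps
precede imaging:

1. **Depth filter.** Samples with fewer than 100,000 total reads are
   excluded (strictly below; a sample at exactly the threshold is kept).
   The threshold is a pragmatic quality floor and is configurable.
2. **Gene mapping.** Features are collapsed to gene symbols using an
   annotation table with a `status` and a confidence `level` per source id.
   Only `known` features are kept; when two ids share a symbol the smaller
   level wins, and at equal level the row with the larger total count is
   kept (the annotation gives no further guidance, and the larger-total row
   is the one that carries the information).
3. **Normalization and VST.** Size factors follow the median-of-ratios
   convention: reference genes are those with no zero count in any sample,
   and a sample's factor is the median ratio of its counts to the
   gene-wise geometric means. Counts are then variance-stabilized under a
   negative-binomial model with the parametric dispersion trend
   `alpha(mu) = a0 + a1/mu`. The closed-form transform

   `v(u) = log2((1 + a1 + 2 a0 u + 2 sqrt(a0 u (1 + a1 + a0 u))) / (4 a0))`

   is strictly increasing, finite at `u = 0`, and behaves like `log2(u)`
   for large normalized counts `u`, so pixel intensities live on a
   log-like scale whose per-gene variance is approximately mean-free.

The trend coefficients are estimated by method-of-moments per-gene
dispersions regressed on `1/mu` (genes with positive dispersion only),
iteratively reweighted with gamma-like weights `1/fitted^2`; after the
initial fit, genes more than 2 natural-log units from the trend are
excluded once. `a0` is floored at `1e-4` so the transform stays defined for
essentially-Poisson data. These details are this package's own choices —
the procedure is deliberately self-contained rather than delegating to an
external normalization package — and all of them are overridable.

**Leakage policy.** The dispersion trend and the image intensity scaler are
fitted on the non-test (training) cohort only and then applied everywhere;
a config switch (`vst_fit = "all"`) restores whole-cohort fitting for
comparison. Size factors are per-sample quantities and are computed for
every sample.

## Image construction

A pathway panel is read from a GMT-dialect file whose description field
carries the category token (`cancer` / `signaling` / `metabolism`).
Whatever the file order, blocks are arranged cancer-first, then signaling,
then metabolism, preserving file order within a block; the full published
panel has 243 pathways and a longest pathway of 345 genes, giving
243 x 345 images. Panel genes never seen in the expression matrix are
pruned from their rows; a pathway left empty is dropped with a warning
(keeping an all-black row would be an equally defensible choice — the
convolution would ignore it — but dropping keeps image height equal to
informative pathway count).

Pixel intensity is global min–max scaling of the transformed expression
over training samples and panel genes, clipped to `[0, 1]` for test
samples that fall outside the training range. Scaling is global rather
than per-image because per-image scaling would erase between-sample level
differences — precisely the signal a classifier must see. Padding beyond a
pathway's length is 0, the same value as "no counts" black; that
conflation is intentional and mirrors the black-to-red rendering, where
the red channel carries the quantized intensity and green/blue are zero.
The network consumes the single-channel grid; RGB is render-only.

## The network

The classifier is a 10-layer network (8 hidden): two unpadded 3x3
convolutions with 4 filters each and tanh activation, a flatten, four
dense relu layers of strictly decreasing width, dropout after the first
two dense layers, and a single sigmoid output — the TEP score in
`[0, 1]`, near 0 for healthy-like and near 1 for tumor-educated profiles.
Training minimizes binary cross-entropy weighted by frequency-proportional
class weights `N/(2 n_c)`; the positive-class weight can be scaled by a
further factor (1.06 reproduces the ovarian-cancer setting). Optimization
uses adadelta (`lr = 1`, `rho = 0.95`, `eps = 1e-7`) with the training
order reshuffled before every epoch.

The published description fixes the layer types and counts but not the
dense widths, dropout rates, epochs or batch size; the defaults here
(256/64/16/4 units, 0.25/0.25 dropout, 50 epochs, batch 32) were chosen to
keep the parameter count modest for a 243 x 345 input and make no claim
of matching the original experimentally selected values. All are exposed
in `network_spec()` / `train_config()`.

The network is implemented from scratch in vectorized R (im2col
convolutions, exact backpropagation — verified against finite differences —
and adadelta), which buys a strict determinism contract: with a fixed seed,
two runs produce bit-identical weights, histories and scores, because
every random draw (initialization, shuffling, dropout) comes from one
seeded stream. Convolutions are `valid`-mode (no padding), as no pooling
or padding is part of the published stack.

## Validation design

`run_study()` reproduces the published harness: a stratified 40% hold-out
(per-stratum `floor(0.4 n)`, which is what reproduces the published
11/12/81 ovarian test set from 28/30/204), stratified 5-fold
cross-validation on the remainder — controls stratified into healthy and
benign subtypes so class balance is preserved in every subset — one model
per fold with the held-in fold as validation monitor, and evaluation of
all five models on the fixed independent test set. A test sample's TEP
score is the mean of its five fold-model scores.

Metrics are the published seven: sensitivity, specificity, balanced
accuracy (their mean — the headline metric under class imbalance),
precision, recall, specificity at 100% sensitivity, and AUC. "Specificity
at 100%" is read as the specificity at the most permissive threshold that
still calls every case positive — the only reading consistent with the
label. Class calls use a fixed 0.5 threshold (the published pipeline
never states one; its score plots imply a continuous output). AUC is the
Mann–Whitney U convention, and cross-validated AUC is the mean of fold
AUCs with an influence-curve standard error pooled across folds (the
method of the cvAUC estimator; a fold-SD normal approximation is
available as a fallback). Whole-percent reporting rounds half away from
zero, which is what turns a balanced accuracy of 0.865 into 87%.

## The synthetic cohort generator

Real platelet cohorts are controlled-access, so the generator makes every
stage testable offline. It emulates: negative-binomial counts with the
dispersion–mean trend `0.05 + 2/mu`; log-normal baseline means
(`ln 50, sd 1`) and library-size factors (`sd 0.2` on the log scale —
enough spread to make size-factor estimation non-trivial but stable); a
class effect of `log2_fc` applied to every gene of designated signal
pathways with sign alternating along the pathway, so the case image
signature is textural rather than a uniform brightness shift (a harder,
more honest test of the convolutional stage); and annotation decoys (2% of
genes get level-2 duplicate ids and unknown-status rows) that exercise the
mapping rules. Fixture panels draw pathway lengths uniformly from 10–80
with a configurable fraction of genes shared between pathways, exercising
pixel multiplicity.

It does **not** emulate isoform-level structure, the ~40k-feature scale of
real splice-variant matrices, batch or flow-cell effects, or realistic
gene–gene correlation beyond pathway-block effects. Passing the end-to-end
tests therefore shows the machinery is correct and can learn a
pathway-structured signal at realistic depth and dispersion — not that it
reproduces clinical accuracy on real cohorts.

## Problem sizes and numerical choices in the test suite

The end-to-end power check uses a 60 case / 60 control cohort, 2,000
genes, 20 pathways with 2 carrying a log2 fold change of 2, and the
default network (criterion: independent-test cvAUC at least 0.90); the
no-leakage guard uses a 100/100 null cohort (log2FC = 0) whose
independent-test cvAUC must stay within [0.30, 0.70]. Dispersion-trend
recovery is checked at 2,000 genes within +/-50% of the generating
coefficients; oracle equivalences (median-of-ratios, pairwise AUC) run on
200 random small instances. Sigmoid outputs are clamped to
`[1e-12, 1 - 1e-12]` inside the loss only; a non-finite training loss
aborts with diagnostics rather than continuing silently.

## Known limitations

- Gene order within a pathway is taken from the panel file and treated as
  canonical; whether a different ordering changes accuracy is untested.
- The model bundle freezes panel, scaler, dispersion trend and fold models
  at training time; prediction on a new cohort never refits anything, and
  by default refuses cohorts missing any panel gene (a tolerance can allow
  small gaps, rendered as black pixels).
- Only two-class decisions are supported (single sigmoid output).
- Training is CPU-bound, single-threaded R; it is sized for panel-scale
  images (tens of pathways in tests), not for very large panels at large
  epoch counts.
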