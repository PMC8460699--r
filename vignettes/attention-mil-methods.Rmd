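---
title: "Methods: slide-level genomic prediction with self-attention MIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slide-level genomic prediction with self-attention MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling assumptions

A whole-slide image carries no tile-level annotation for a genomic label:
whether a patient carries a TP53 point mutation is a property of the
patient, while the morphological correlates of that mutation — if any —
appear in an unknown subset of tumor tiles. `wsimil` therefore treats
each patient as a *bag* of tile instances and learns a bag-level
classifier (multiple-instance learning). Two assumptions follow:

* **Permutation invariance.** A slide has no canonical tile order, so the
  aggregator must be invariant to row permutations of the bag. Mean
  pooling and row-wise self-attention both satisfy this; the package
  asserts it in tests to 1e-5 (float reassociation).
* **Frozen features.** Tile features come from a fixed, deterministic
  extractor; only the small aggregation head is trained. This keeps
  training at desk scale (bags are cached matrices) and makes the
  extractor an exchangeable component behind a declared contract
  (`feature_extractor()`): any map from a prepared tile tensor to a
  fixed-length vector that is deterministic in evaluation mode. The
  shipped implementation is a seeded Gaussian random-projection extractor
  (`projection_extractor()`, default D = 2048); convolutional backbones
  satisfying the same contract plug in without touching the pipeline.

## The head, exactly

With `x` the N×D bag, `h = ReLU(FC2(ReLU(FC1(x))))` gives N×128 hidden
rows (FC widths 512 and 128). The self-attention layer computes
`f = h W_f`, `g = h W_g` (width `d_attn`), scores
`s[j, i] = f(h_i) · g(h_j)`, and `alpha = softmax` over `i` within each
row `j`. Outputs are `o_j = sum_i alpha[j, i] h_i`, the residual is
`y = h + gamma * o`, the pooled vector is the row mean of `y`, and a
128→2 layer with softmax produces the class probabilities. Cross-entropy
is the loss; the positive-class probability is the score for AUC.

Two index conventions here were genuinely open and are the package's own
resolutions, documented rather than asserted as anyone's intent:

* **Softmax axis.** The softmax runs over the *input* index `i` for each
  output `j` — each output attends over all tiles, making `alpha`
  row-stochastic. The opposite axis would make every column sum to one,
  and the tile weight below would degenerate to the constant `1 + gamma`
  for every tile, contradicting the very purpose of a weight map in which
  tiles differ.
* **Weight orientation.** The per-tile weight `beta_i = 1 + gamma *
  sum_j alpha[j, i]` aggregates attention *received* by tile `i` (a
  column sum). Under row-stochastic `alpha` this varies across tiles and
  totals `N * (1 + gamma)` — an invariant the tests assert on every
  forward pass.

`d_attn` is not pinned by the training recipe; the default 16 (= 128/8,
the head-width convention of the self-attention literature) is a
configurable `mil_config()` entry. The hidden nonlinearity between FC
layers is likewise unstated in the recipe; rectified-linear units are
used after both.

## Training

Adam for 30 epochs, learning rate 1e-4 for all parameters except `gamma`
(1e-3), `gamma` initialised to 1, effective bag batch of 8. Because bags
have variable N, bags are processed one at a time and gradients are
accumulated to the effective batch — the loss is exact and no padding or
masking is needed. Gradients are analytic (hand-derived backprop through
the attention softmax and residual pooling) and are verified against
central finite differences in the unit tests at 1e-4 relative tolerance.
Model selection keeps the epoch with the best validation AUC (AUC is the
pipeline's sole reported metric, so "best on validation" is read as best
AUC; ties go to the earlier epoch). All randomness — initialisation and
batch order — flows from `mil_config(seed)`.

Class imbalance is reported (per-task positive counts on the label
table), not corrected: no re-weighting or oversampling is applied.

## Preprocessing choices

* **Tiling.** Nonoverlapping 512 px tiles; partial edge tiles dropped;
  row-major order; the input raster is taken to be at the working
  magnification already (no pyramid logic — the method is
  magnification-agnostic and synthetic inputs have no pyramid).
* **Background.** A tile is background iff its mean pixel value over all
  pixels and channels is *strictly* greater than 220 (0–255 scale). The
  filter runs before clustering, so background tiles never enter k-means;
  running the filter first matches the stage order of the pipeline
  diagram and costs nothing.
* **Tumor selection.** k = 2 k-means (10 restarts, seeded) on 128×128
  area-downsampled, flattened tile vectors (49,152 values). Mapping the
  two clusters to tumor/nontumor is done by the lower-mean-intensity
  centroid — tissue is darker than background and stroma — because the
  original mapping step is a pathologist's judgement and not automatable;
  `apply_refinement()` accepts per-tile overrides exactly so that a human
  can correct both cluster mapping and artefacts. Degenerate input (all
  tiles identical, one empty cluster) warns and labels everything tumor
  rather than failing, which keeps very small slides usable.
* **Colour normalization.** The normalization is specified through
  slide-level per-channel pixel mean and standard deviation only, so the
  implementable contract is the per-channel affine map
  `(in − mean_src)/sd_src * sd_tgt + mean_tgt`, clipped to [0, 255],
  applied with identical source statistics to every tile of a slide. It
  is idempotent once source equals target (tested). Stain-deconvolution
  methods are deliberately out of scope.
* **Resampling.** All downsampling/resizing uses area (box)
  interpolation, implemented as sparse row/column averaging matrices:
  deterministic, exact for integer ratios, and `side = 1` provably
  returns per-channel means.

## Labels

Pathway activity is the weighted *mean* (not sum) of member-gene values:
the 1/N_gene prefactor is part of the printed formula and wins over
looser prose. Weights are +1 (oncogene) / −1 (suppressor); the binary
label is 1 exactly when the score is positive — zero is inactivated.
Member genes missing from the table, or NA values, are dropped with the
member count adjusted (and a warning) rather than zero-imputed, which
would bias scores toward zero. Gene selection keeps point-mutation genes
at prevalence ≥ 3% and CNA genes strictly > 5%. The CNA binarization
convention is configurable (`nonzero` or `level2` on GISTIC-style
−2…2 calls) because discrete-call semantics differ between sources; the
default treats any nonzero call as altered. The shipped
`pathways_default.tsv` is an illustrative, user-editable subset of the
ten canonical pathways' member genes — the full curated catalog is an
input, not hard-coded biology.

## Splits, AUC, transfer

`split_patients()` uses largest-remainder apportionment (floor each
`n·r`, give the remainder to the largest fractional parts, ties to the
earlier partition). This convention uniquely reproduces the reference
cohort sizes: 659 → 461/99/99 at 70/15/15, 350 → 70/280 and 316 → 63/253
at 20/80. Splits are at patient level; the pipeline keeps one slide per
patient, so no cross-slide leakage logic is needed.

AUC is the midrank Mann–Whitney statistic (ties count one half). The 95%
interval is the percentile bootstrap over 1000 patient resamples;
replicates that draw a single class are redrawn, not skipped, so exactly
1000 replicates enter the interval. DeLong intervals, cross-validation
and calibration are out of scope.

Transfer (`finetune()`) freezes FC1/FC2 — their checksums are asserted
unchanged — and updates only `W_f`, `W_g`, `gamma` and the output layer.
Task eligibility in the new cohort respects the same prevalence rules as
gene selection (> 3% point, > 5% CNA).

## What the synthetic generator emulates — and what it does not

`generate_slide()` plants three tile populations: background uniform in
[230, 255] per channel and tissue textured in [80, 200], guaranteeing
strict separation around the 220 threshold so the filter's behaviour is
deterministic in tests; signal tiles additionally carry a distinct colour
tint, so one planted truth exercises both k-means separability and
downstream recovery. `generate_feature_bags()` plants instance-level
signal directly in feature space: flagged instances are shifted by a
chosen effect size along a fixed unit direction, and a bag is positive
iff it contains a flagged instance. `generate_omics()` plants per-gene
Bernoulli prevalences and a per-patient activity sign per pathway that
member-gene expression and CNA follow, so the weighted-mean score
recovers the planted sign.

These are caricatures by design: no H&E texture realism, no pyramidal WSI
containers, no tile-to-tile spatial correlation, no label noise, and the
feature-space signal is a clean mean shift. A passing recovery test
therefore shows the machinery — selection, attention, training, transfer
— is correct, not that real-cohort AUCs are attainable; results on real
cohorts depend on external slide archives and a pretrained convolutional
backbone and are outside the package's test loop.

## Study conditions used by the tests and acceptance script

The synthetic recovery experiment uses 200 training / 100 validation /
100 test bags of 20–50 instances, feature dimension 32, signal fraction
0.3 and effect size 4 — sizes chosen as a realistic desk-scale analogue
of per-cohort patient counts, with the effect large enough that an
instance-level linear probe reaches AUC > 0.95, so failure isolates the
aggregator rather than the data. The null control sets the effect to 0
and expects chance-level AUC (band 0.35–0.65 across seeds). The transfer
experiment trains the source model on one signal direction and
fine-tunes on 60 bags of an orthogonally shifted domain; with FC1/FC2
frozen, improvement over the unadapted model across 5 seeds is the
success criterion. The demonstration pipeline uses 24 simulated patients
with 10×8-tile slides of 16 px tiles and a 32-dim extractor so the whole
image-to-metrics chain runs in seconds.

## Known limitations

* The projection extractor is linear in (downsampled) pixels; it
  separates colour/intensity-coded signal but not texture that only a
  deep backbone would resolve.
* Attention is O(N²) in bag size; whole slides with tens of thousands of
  tumor tiles would need chunking or sparsification that the package does
  not implement.
* The weight-map rendering min–max scales log-weights per slide (natural
  log); absolute brightness is therefore not comparable across slides,
  only ranks within a slide. When all weights are equal the rendering is
  uniform full intensity by convention.
* Bootstrap intervals on very small test sets (the demo pipeline's
  handful of test patients) are honest but nearly vacuous; the metrics
  JSON records `n_test` for exactly this reason.
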