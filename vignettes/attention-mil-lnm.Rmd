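---
title: "Attention-based MIL for LNM prediction: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based MIL for LNM prediction: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lnmil)
```

## The problem

After endoscopic resection of a T1 colorectal cancer, guidelines send
every patient with a high-risk histologic feature to additional surgery
with lymph-node dissection — yet only a minority of those patients
actually harbour lymph node metastasis (LNM), so most of these
operations are, in hindsight, unnecessary. `lnmil` implements a
weakly supervised image model for this decision: predict LNM directly
from the H&E-stained whole-slide image (WSI), with no pixel-level
annotation, and quantify how many unnecessary operations such a model
would avoid relative to the operate-on-everyone rule, at the price of
how many missed metastases.

## The model and its assumptions

A WSI is treated as a *bag* of patches under multiple instance learning:
only the bag (patient) carries a label, and the model must discover
which patches matter. The pipeline is:

1. **Tissue detection.** Otsu thresholding on the HSV saturation
   channel, then removal of connected components smaller than one patch
   area. Near-white rasters short-circuit to an empty mask (Otsu would
   otherwise split scanner noise). Assumes stained tissue is more
   saturated than background — true for H&E and for the generator.
2. **Tiling.** A non-overlapping grid of p×p patches (default 256 px at
   full scale, 64 px in the desk-scale configurations), keeping cells
   with at least 50% tissue. Trailing partial rows/columns are dropped —
   a half-open grid keeps patch counts exactly reproducible by a
   brute-force count, which the test suite exploits. Padding schemes
   were rejected for that reason.
3. **Feature extraction.** Patches are mean-pooled to 32 px and encoded
   by four stride-2 3×3 convolution blocks (8/16/32/64 channels), global
   average pooling and an affine map to a 512-dimensional feature — the
   one dimension the pipeline treats as fixed. The extractor is
   pretrained as a patch classifier with *bag-inherited* labels
   (every patch of a positive slide counts positive), a deliberately
   noisy supervision that suffices because only a texture-level
   contrast must be learned. The classification head is then discarded.
4. **Attention pooling.** Two-layer tanh attention (hidden width 128,
   gated variant behind a flag) produces one logit per patch;
   a softmax turns these into attention scores in [0, 1] summing to 1.
   The slide feature is the score-weighted average of patch features —
   permutation-invariant by construction, which the suite asserts.
5. **Classification.** A single logistic unit on the 512-d slide
   feature.

The network is written in vectorised base R (im2col convolutions,
analytic backprop, Adam). This is a deliberate design decision, not a
shortcut: the model *is* the package's subject, and every gradient is
checked against central finite differences in the tests. The encoder
can be frozen after pretraining (default: attention and classifier only
are trained end to end, which is faster and stable at desk scale) or
fine-tuned end to end (`freeze_fe = FALSE`).

Class imbalance is handled by weighting the cross-entropy inversely to
class frequency, in both pretraining and MIL training. Bags above 500
patches are subsampled (seeded, per epoch) during training only.

## The synthetic data generator

No public data accompany this problem setting, so the generator is a
first-class module that emulates the *statistical structure* of such a
cohort rather than its biology:

* two specimen strata — endoscopic resections (17.8% LNM prevalence,
  small tissue fragments, uniform extent 10–25% of the raster) and
  surgical resections (6.6%, 30–60%) — with deterministic positive
  counts (nearest integer of n×prevalence) by default and a binomial
  mode behind a flag;
* clinicopathologic covariates drawn per specimen×LNM stratum from the
  published summary distributions (medians/IQRs for age, BMI, size,
  invasion depth; proportions for the categoricals). Covariates are
  sampled independently (no copula): their only purpose is to give the
  random-forest baseline the label signal the real risk factors carry
  (lymphovascular invasion 53.5% vs 11.4% in surgical positives vs
  negatives, and analogous gaps for budding and differentiation).
  A non-informative mode removes that signal for null checks;
* 10% of patients contribute a second slide, so slide counts exceed
  patient counts, exercising the slide-to-patient aggregation. The
  source tables imply multi-slide patients without stating the rate;
  10% is this package's choice, fixed once;
* slides are near-white rasters with one smooth tissue blob (largest
  connected component of a thresholded smooth random field) textured as
  pink stroma with sparse dark nuclei; positive slides have 5% of the
  tissue area overwritten with a high-frequency, strongly saturated,
  hyperchromatic "evidence" texture (budding/micropapillary-like foci
  around a few seeded centers), recorded in a ground-truth mask. The
  evidence texture is chosen to differ from normal texture in
  second-order statistics so a small CPU-trainable encoder can separate
  it, and to be *more* saturated than normal stroma so it always
  survives the saturation-based tissue detector.

What the generator does **not** emulate: stain chemistry and scanner
colour profiles, pyramidal multi-resolution files, nuclear morphology,
spatial correlation between covariates and image content (a positive
slide's covariates and its evidence texture are conditionally
independent given the label). Consequently, a passing benchmark shows
the *pipeline* learns and localizes a planted minority texture from
bag-level supervision — it says nothing about performance on real
histology, where the discriminative signal is far subtler.

## Evaluation protocol

The four **versions** reproduce an internal-validation design that
contrasts specimen types: one global class×specimen-stratified 80/20
patient-level split is drawn; version 2 uses it as-is, version 3
restricts the test side to surgical patients, version 4 to endoscopic
patients, and version 1 restricts both sides to surgical patients. The
published composition describes the versions separately, but its
arithmetic (test sets of versions 3 and 4 summing to version 2's) is
consistent with a shared randomization, which is therefore the default;
independent draws are available by varying the seed per version.
Training counts use floor(0.8·n) per stratum with largest-remainder
reallocation against the per-class total, ties toward the endoscopic
stratum — the rule that reproduces the published table exactly
(e.g. 57 + 80 = 137 training positives).

Within the training set, patients are dealt into five folds stratified
by class×specimen (round-robin with rotating start), so each fold
preserves the class proportion to within one patient. Each fold model
trains on the other four folds; the five models are ensembled on the
held-out test set by averaging probabilities per slide, then averaging
slides per patient (the aggregation rule is unstated in the source
design; the mean is this package's choice).

The operating threshold maximizes the Youden index J = sensitivity +
specificity − 1 over all midpoints between adjacent distinct scores
(±∞ included), ties toward higher sensitivity then lower threshold.
Whether the original cutoffs were chosen on CV or test predictions is
not documented; the default here applies it to the test predictions the
caller passes, and the choice is the caller's. McNemar's test compares
per-patient correctness of the model against the all-positive rule:
exact two-sided binomial below 25 discordant pairs, continuity-corrected
chi-square above. The published comparison prints one p-value per
metric row, which is not reconstructable from per-patient data; this
package reports one p per paired comparison and notes the divergence.
The random-forest baseline (500 trees) uses the same folds and the same
ensembling.

## Numerical choices

* Percentages print with half-up rounding (one decimal; two for the
  lymph-node ratio), matching clinical reporting conventions;
  `round_half_up()` exists because R's `round()` is round-half-even.
* Count reconstruction from printed rates uses nearest-integer rounding
  of rate×n — the bridge that turns a published sensitivity/specificity
  pair plus class sizes back into a confusion matrix.
* The reduction in unnecessary surgery is the difference of the two
  *rounded* percentages, matching published arithmetic.
* Attention softmax subtracts the max logit; scores sum to 1 within
  1e-6 on every bag (asserted).
* Constant attention vectors min-max normalize to all zeros — a bag
  with no informative patch renders as visually null rather than
  uniformly warm.
* Largest-remainder ties, Youden ties and top-patch ties all have
  documented deterministic tie-breaks (endoscopic stratum first, higher
  sensitivity then lower threshold, row-major anchors).
* All randomness flows through explicit integer seeds; child seeds are
  derived per stage so stages can be regenerated independently.

## Benchmark scale and what the tests show

The standing benchmark (`synthetic_benchmark()`) uses 227 patients
(~250 slides) at 512 px rasters, 64 px patches and 15% prevalence —
sizes chosen so the full pipeline (rendering, tiling, pretraining,
MIL training, a permutation null and localization scoring) completes in
minutes on one CPU while keeping ≥30 positive bags in play. Three
read-outs summarise it: held-out bag-level AUC (the generator's planted
signal makes ≥0.90 attainable), a label-permutation null, and attention
localization.

The null is the standard permutation test: bag labels are permuted
jointly across training and test bags, the attention/classifier head is
retrained on the permuted training labels, and the held-out AUC is
scored against the permuted test labels; the reported null AUC is the
mean over 16 permutations. Two tempting shortcuts fail here and are
worth recording. Permuting training labels only and scoring against the
*true* test labels yields a bimodal statistic (observed draws from
~0.03 to ~0.98): the evidence feature is so separable that the head
amplifies the tiny sample correlation between evidence and the permuted
labels — with a random sign — into an extreme ranking; that statistic
is also biased below 0.5, because the over-parameterised head
(512 features, ~200 bags) loads the shared evidence direction toward
the *majority* permuted label of the evidence bags, which under 15%
prevalence is negative. Neither class-weighting variants nor weight
decay remove the effect. The joint permutation sidesteps both problems:
whatever the head learns, it is scored against labels that are random
with respect to it, so the per-draw AUC concentrates near 0.5 (sd
~0.14 at ~50 test bags) and the permutation mean is a stable null
estimate.

Localization asks that in at least 90% of
positive test bags, evidence-bearing patches receive a higher
mean normalized attention score than normal patches. The encoder uses
global *max* pooling rather than average pooling: evidence foci can
straddle patch boundaries, leaving a patch with, say, a quarter of its
area covered, and average pooling dilutes such a partial response into
the normal-texture range (an observed failure mode: a positive slide
whose best patch had 25% evidence coverage was missed outright),
whereas max pooling keeps the focal response strong. Patch-level
evidence discrimination is scored as balanced accuracy at the
balanced-optimal threshold, because the pretraining head's intercept
reflects the class weights, not the texture separation.

## Known limitations

* The synthetic signal is strong and localized; real budding foci are
  rarer, subtler and confounded with stain variation. Expect the AUC
  gap between this benchmark and real cohorts to be large.
* The encoder is small by design; swapping in a deeper backbone is
  supported structurally (`fe_config()`) but untrained weights are the
  only option offline.
* Patient-level covariates are independent of image content, so joint
  image+covariate models cannot be studied with this generator.
* Version splits reuse one randomization by default; drawing the four
  versions independently changes the nesting identities the tests
  assert.
* The McNemar p-value is one per comparison, not one per metric row.
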