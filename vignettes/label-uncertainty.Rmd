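---
title: "Training with reader disagreement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training with reader disagreement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SpectCertainty)
```

## The problem

Binary classification of dopamine-transporter (DAT) SPECT — "normal"
versus "Parkinson-typical reduction" of the striatal signal — contains
a stubborn 5–10% of genuinely borderline scans.  When several trained
readers label such a cohort independently, they disagree almost
exclusively on those borderline cases: the disagreement is caused by
*class overlap* (the two classes genuinely overlap in image space), not
by sloppy annotation.  A convolutional network trained on a single
collapsed label per scan is blinded to that information, its sigmoid
output clusters hard at 0 and 1, and the distance of the output from
the 0.5 decision threshold becomes a poor flag for "this case should
not be auto-reported".

This package implements and evaluates three ways of turning a panel of
R binary reader votes into the training target:

* **MVT** (majority-vote training): the target is the majority vote,
  a hard 0/1 label; binary cross-entropy loss.
* **RVT** (random-vote training): at *every presentation* of an image
  the target is one of the R votes drawn uniformly at random from a
  single run-level random stream (seeded once, never reset between
  epochs); binary cross-entropy loss.  In expectation the target equals
  the vote proportion.
* **AVT** (average-vote training): the target is the proportion of
  "reduced" votes, k/R (0, 1/3, 2/3, 1 for R = 3); mean-squared-error
  loss on the sigmoid.

Downstream, an **inconclusive interval** on the sigmoid output is
anchored on validation data: for a target proportion p of n validation
cases, the k = round(p·n/2) cases closest to the threshold on *each*
side are selected (the equal-sided rule makes the interval asymmetric
around 0.5).  Test cases inside the interval are flagged inconclusive,
the rest certain.  Performance is summarized by the balanced accuracy
(mean of sensitivity and specificity) in the certain cases as a
function of the observed inconclusive proportion, integrated over
0.2%–10% by the trapezoid rule and scaled to its maximum (the
*certainty-curve AUC*).  Methods are compared across K random splits
with the Nadeau–Bengio corrected resampled t-test,
t = mean(d) / sqrt((1/K + n₂/n₁)·var(d)), which inflates the variance
to account for overlapping training sets; for the 60/20/20 design the
test-to-train ratio is 1/3.

## The synthetic cohort

No clinical data ship with the package.  The generator produces a 2D
slab phantom — a smooth brain-shaped background plus, per hemisphere, a
caudate and a putamen intensity blob whose plateau is
`striatalContrast` (default 4) times the background — on a 64×64 grid
at 3 mm/pixel.  A latent severity s ∈ [0,1] scales the blobs down,
putamen before caudate, mimicking the posterior-to-anterior reduction
pattern; asymmetry hits one hemisphere harder.  The acquisition chain
is: template → Gaussian point-spread blur (10 mm FWHM in
distribution) → additive Gaussian noise (5% of background) → optional
post-reconstruction smoothing.  Each scan yields 2 reconstruction
variants (ASC and NOASC, implemented as a background offset plus
contrast rescale) × 6 smoothing levels (0, 10, 12, 14, 16, 18 mm FWHM;
`sigma = FWHM / (2·sqrt(2·ln 2))`), i.e. 12 instances.  The source
lists five smoothing kernels but counts six levels; the sixth is taken
to be the unsmoothed reconstruction — a documented interpretation.

Severity is drawn from a three-part mixture: a clearly-normal Beta
component on [0, 0.40], a clearly-reduced mirrored component on
[0.60, 1], and a **uniform boundary band** on [0.44, 0.58] carrying 8%
of the mass.  Readers threshold severity plus N(0, 0.012) perceptual
noise at personal cutpoints (0.462, 0.511, 0.546).  Those six numbers
were calibrated **once**, by numerical integration of the exact
vote-pattern probabilities (`votePatternProbs()`), against the
published development-cohort table — 49.1% unanimously normal, 2.8%
reduced-by-one, 2.0% reduced-by-two, 46.1% unanimously reduced (95.2%
unanimity) — and then frozen.  A 20,000-scan Monte-Carlo draw
reproduces all four frequencies to within a few tenths of a percentage
point.

Two out-of-distribution profiles emulate external test sets: PPMI-like
(1.3× wider point-spread, 1.2× noise, 67.9% prevalence) and MPH-like
(0.65× point-spread, 1.3× contrast, 0.5× noise, 51.1% prevalence),
each with a single unsmoothed instance per scan and a single reference
label.

What the generator does **not** emulate: projection-space physics,
attenuation/scatter, spatial normalization, anatomical variability,
scanner-specific artefacts, or reader drift.  Passing tests therefore
demonstrate that the *methods* behave as described on a severity-
monotone imaging feature with calibrated label uncertainty — not that
any clinical accuracy figure transfers to real data.

## The network and its training

The classifier is a ResNet-18 reduced to one input channel and one
sigmoid output: 7×7/2 stem convolution (no bias) + batch norm + ReLU +
3×3/2 max pool, four stages of two basic blocks with widths
(64, 128, 256, 512) and projection shortcuts at stage transitions,
global average pooling, and a 512→1 linear head.  With affine batch
norms this gives exactly 11,170,753 parameters, reconciled layer by
layer in `parameterAccount()` (stem 3,136 + 128; blocks 73,984,
73,984, 230,144, 295,424, 919,040, 1,180,672, 3,673,088, 4,720,640;
head 513).  Convolutions use He initialization; the head uses the
standard uniform fan-in scheme (the He prescription covers the
convolutional layers only).

The training engine — im2col + BLAS GEMM convolutions with full
backward passes, batch norm, max-pool argmax bookkeeping and Adam — is
implemented in Rcpp/RcppArmadillo in single precision.  Gradients are
verified against central finite differences in the test suite.
Training follows the reference protocol: Adam at learning rate 1e-4,
batch size 64, mean loss reduction, no weight decay, no schedule, no
early stopping; final-epoch weights are used (no best-validation
checkpointing, which the protocol does not mention).  Inputs are
normalized per image by the mean over a geometric background region (a
DVR-like convention); evaluation is per image instance, in evaluation
mode (running batch-norm statistics).

**Desk scale.**  The package's default experiment
(`experimentConfig()`) uses a 200-scan cohort of 64×64 slabs, a
width-0.25 network (same depth and topology, stage widths
16/32/64/128), K = 3 split realizations and 12 training epochs.  Width
and size were chosen so a full 3-method × 3-split experiment runs in
minutes on one CPU; 12 epochs is the shortest training length at which
hard-label training reaches the saturated-sigmoid regime that the
reference 20-epoch protocol produces — with substantially fewer
epochs the network still assigns mid-range sigmoids to heavily
smoothed instances of unambiguous scans, which inflates the middle of
the validation sigmoid distribution and masks the interval pathology
of MVT that the conclusiveness analysis is about.  A 224×224
full-width mode exists for architecture-fidelity checks and is not
trained in the tests.

## Numerical and design choices

* **Interval bounds.**  The source defines the interval by its member
  cases; the exact bound convention is unreported.  Bounds here sit at
  the midpoint between the outermost selected case and its nearest
  excluded neighbour (or at the side's extreme when a whole side is
  selected), so re-applying an interval to the sigmoids that built it
  recovers exactly the selected 2k cases; membership is inclusive,
  `lower <= s <= upper`.  Exact value ties across the boundary can
  over-cover; with continuous sigmoids this has probability zero.
* **Rounding and ties.**  k = round(p·n/2) rounds half *up*
  (deterministic); distance ties within a side break by case order.
  Sigmoids exactly at 0.5 count as "below", consistent with the
  "sigmoid ≤ 0.5 means normal" decision rule.
* **Degenerate strata.**  Balanced accuracy in a stratum missing a
  class is NA and propagates as a curve gap, never imputed.  A test
  set in which every interval lands the same observed proportion
  yields a constant certainty curve; its scaled trapezoid AUC is that
  constant (this occurs when a small test subset happens to contain no
  borderline scan).
* **AUC integration** runs over *observed* proportions with linear
  interpolation to the 0.2%/10% endpoints and constant extrapolation
  when no observed proportion reaches an endpoint; duplicate abscissae
  collapse to the largest-target point.
* **RVT stream.**  Random votes are drawn per (image, presentation),
  not pre-assigned per epoch; whether the original implementation
  resampled per batch iteration or per epoch is unstated, and
  per-presentation draws are the minimal-bookkeeping reading of
  "different votes could be selected at every training epoch".
* **Even panels.**  Majority-vote ties (impossible for R = 3) break
  toward "reduced", the clinically conservative call; configurable.
* **Seeds.**  Every stage derives its own 31-bit stream from one
  master seed via a stable counter scheme (`deriveSeed()`); cohorts,
  splits, initializations and RVT draws are bit-reproducible.
* **Confidence intervals** in the distance-by-consistency summary use
  the normal approximation, mean ± 1.96·se.
* **rho** in the corrected t-test defaults to the 60/20/20 design's
  test/train ratio 1/3 and is overridable.

## What the desk experiment shows

`runExperiment()` trains the 3 × K networks, anchors the 50-interval
grid (targets 0.2%–10% in 0.2% steps) on each network's validation
sigmoids, and reports: balanced accuracy; the mean distance to the
threshold of between-reader-consistent versus -discrepant validation
cases; the certainty-curve AUC on the in-distribution test subset; and
observed-versus-target regression slopes (through the origin) on the
two out-of-distribution cohorts.  Across the seeded desk runs the
qualitative picture of the full-scale study reproduces: discrepant
cases sit markedly closer to the threshold than consistent ones under
all three schemes, and the separation is larger for RVT/AVT than for
MVT; MVT's 5% interval swallows most of the sigmoid range while
RVT/AVT keep it moderate; and on the out-of-distribution cohorts MVT's
observed inconclusive proportions deviate far more from the intended
targets than RVT's.  The numeric values are produced at run time by
`scripts/acceptance.R` and the test suite; none are hard-coded.

## Limitations

The phantom's severity-to-intensity mapping is one-dimensional, so the
desk task is far easier than clinical classification (balanced
accuracies near 100% are expected and carry no clinical meaning).
Interval stability across realizations is summarized at K = 3, which
is enough for direction but not for the standard deviations a K = 10
study reports.  The engine is CPU-bound single-precision; it is meant
for desk-scale experiments, not for training the full-width network.
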