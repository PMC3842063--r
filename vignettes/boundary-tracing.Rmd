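---
title: "Probabilistic breast-boundary tracing: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic breast-boundary tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammotrace)
```

## The problem

In a mammogram the breast region fades into a near-black, noisy background.
The transition zone — the breast boundary — is not an intensity edge: the
compressed tissue thins out gradually, so thresholding and gradient-driven
active contours are unreliable there. What *does* distinguish the boundary
is its texture. `mammotrace` treats boundary extraction as sequential
probabilistic tracing: starting from an automatically detected seed pixel,
the boundary is grown one pixel at a time, and each step accepts the
candidate pixel `P_c` maximizing the joint score

    P(T) x P(P_c | P_k, P_k-1) x P(P_c)

where

* `P(T)` is a calibrated probability that the texture of the window around
  the candidate belongs to the *boundary* class (an RBF-kernel SVM over
  PCA-reduced local-binary-pattern histograms);
* `P(P_c | P_k, P_k-1)` is a bivariate Gaussian density over the pair of
  slope angles formed by the candidate and the two previously accepted
  points — the smoothness model;
* `P(P_c)` is a lower-branch Laplace density of the texture probability
  itself — a prior that sharpens the preference for high texture
  probabilities, compensating for the logistic calibration's flat response
  near 1.

The same machinery, retrained on pectoral-muscle ground truth, extracts the
pectoral boundary; no separate code path exists.

## Texture model

**LBP codes.** Each pixel receives an 8-bit code: bit `i-1` is set iff
neighbor `z_i` is *strictly brighter* than the center (`delta(u) = 1` iff
`u >= 1`). This threshold is deliberate and differs from the common LBP
convention `u >= 0`; the common form is available as `strict = FALSE` but
the strict form is the default. Neighbors are ordered clockwise from the
top-left; any fixed order works as long as training and tracing agree.
Codes are computed for border pixels too, on a 1-px replicate-padded image
— the initialization scan must be able to evaluate every pixel.

**Window descriptor.** The even `window x window` crop centered on a pixel
(default 50) is split into four equal quadrants; each contributes a raw
256-bin histogram of its LBP codes, concatenated (top-left, top-right,
bottom-left, bottom-right) into a 1024-vector. Histograms are left as raw
counts: PCA centering absorbs the overall scale, and count histograms keep
the quadrant-mass invariant (`(window/2)^2` per block) exact, which the
tests exploit. Window crops at the image rim are clamped with edge
replication so every pixel has a descriptor.

**PCA.** The basis is the eigen-decomposition of the sample covariance of
all training descriptors; the retained dimension is the smallest index at
which the cumulative eigenvalue fraction exceeds 0.99. On phantom data this
keeps a few hundred components. PCA is fitted on positives and negatives
together.

**SVM and calibration.** A C-classification RBF SVM (via `e1071`/libsvm)
is trained on standardized PCA scores. Hyperparameters come from a
logarithmic grid — cost `2^-5 .. 2^15`, kernel width `2^-15 .. 2^3`, both
in steps of `x4` — scored by stratified 5-fold cross-validated accuracy;
ties resolve to the first grid point, making selection deterministic given
the seed. Class probabilities use a Platt sigmoid of the decision value,
fitted by Newton iterations on *out-of-fold* decision values: with two
classes the pairwise-coupling construction reduces exactly to this single
sigmoid, and out-of-fold values avoid the optimistic bias of training-set
decision values. Classification is `boundary` iff the calibrated
probability is at least 0.5 (ties to boundary), so probability and class
are consistent by construction.

**Training samples.** Positives are every ground-truth boundary pixel plus
its immediate left and right neighbors; negatives are uniform random
pixels, redrawn until none lies within an exclusion Chebyshev radius
(default half the window, 25 px) of the boundary, a fixed count per image
(default 900). Sample collection is deterministic given its seed.

## Smoothness model

For consecutive boundary points the slope vector pairs the newest segment
angle with the previous one, each computed as `atan2(dx, dy)` with the
x-difference (column difference) as the *first* argument — an unusual but
harmless convention retained verbatim so that training and tracing agree.
A maximum-likelihood bivariate Gaussian (divide-by-N covariance, plus
`1e-6` on the diagonal against near-singular fits) models these pairs. At
trace time the candidate plays the role of the newest point. Angle
residuals are wrapped into `(-pi, pi]` before the quadratic form — slopes
are circular, and although the fitted cluster is tight enough that
wrapping rarely fires, it prevents spurious near-zero densities at the
±pi seam. The standard normalizer `1/(2*pi*sqrt(det(Sigma)))` is used; a
shared constant never changes which candidate wins.

## Laplace prior

`laplace_prior(x) = exp(-(mu - x)/beta) / (2*beta)` on `x in [0, mu]`,
with `mu = 1`, `beta = 0.05` by default: only the rising branch of the
Laplace density, peaking at certainty. Its defining property is
log-linearity — every `beta` of additional texture probability multiplies
the prior by `e`, regardless of where on the scale the step occurs — which
is what makes it sharpen comparisons among candidates whose sigmoid
probabilities are all close to 1. With `mu = 1` the clamp branch
(`x > mu`) is unreachable; it exists only for user-supplied `mu < 1`.

## Tracing

Initialization scans rows top to bottom; the first row containing any
boundary-classified pixel is evaluated in full and its maximum-probability
pixel (leftmost on ties) becomes the seed. Under marginalization over the
unknown history, the smoothness factor integrates out and the prior does
not change the argmax, so only the texture probability is compared.

Each subsequent step considers every pixel of the punctured Euclidean disk
of radius `r` (default 20) around the current head, in row-major order,
minus pixels within a revisit-exclusion Chebyshev radius (default `r/2`)
of any previously accepted point — the exclusion zone is what keeps the
trace moving forward without assuming an orientation. Candidates not
classified `boundary` are dropped; the survivor with maximal joint score
is appended, ties again row-major. The second step has a single history
point, so the smoothness factor is undefined and the score is texture (x
prior in TSP mode); from the third step on, the full product applies. The
ablation modes `T`, `TS`, `TSP` disable factors accordingly, and
`ablate_modes()` runs all three sharing one per-pixel texture-probability
cache, since that factor is mode-independent.

Termination: no boundary-classified candidate remains, `max_steps`
(default 4000) is reached, or the accepted point touches the image border
*while more than one radius away from the seed* — the seed region
legitimately touches the border where the breast curve enters the frame,
and without that carve-out a trace starting on the top row would stop
immediately. The loop contains no randomness; identical inputs give
bitwise-identical boundaries.

## Evaluation metrics

`acc_mean` is the mean, over extracted points, of the perpendicular
distance to the line through the point's two nearest distinct ground-truth
points. The distance uses the slope-free cross-product form, which unlike
the slope-intercept formula is defined for vertical segments. When several
ground-truth points tie as second-nearest, a point adjacent (in
ground-truth order) to the nearest is preferred: the intended local line
is the one between neighbors. The measure is deliberately asymmetric in
its arguments. `curve_measure` sums squared first- and second-difference
norms over interior points; endpoints contribute nothing. It is invariant
to translation and rotation, and `curve_diff` compares the smoothness of
an extraction with its ground truth.

## Baselines

The greedy active contour moves each vertex, in index order, to the
position in an odd search window minimizing `alpha*E_ext +
beta*||v_i - v_{i-1}||^2 + gamma*||v_{i+1} - 2 v_i + v_{i-1}||^2`, with
neighbor positions frozen at the start of the iteration and terms dropped
at the contour ends. The external energy is the negated gradient magnitude
of the Gaussian-smoothed image. Note the naming wrinkle: the first
difference is conventionally called *continuity* and the second
*curvature*; the weights here stay attached to the formulas as written
above. The threshold baseline is Otsu's threshold, the largest connected
foreground component, a 3x3 morphological closing, and the per-row
extremal foreground pixel on the background side as the boundary trace.

## The phantom generator

`generate_phantom()` emulates the gross structure of an MLO-view
mammogram at configurable size (default 512 x 512): a smooth open curve
from the top edge to the bottom edge, monotone in row and bulging
rightward, built as a natural spline through seeded random control points
(5 by default; more gives a wigglier curve); left of the curve an interior
ramping from 40 at the boundary to 180 deep inside (ramp length 120 px),
carrying multiplicative correlated speckle (Gaussian-filtered noise,
correlation length 5 px, amplitude 0.10); a 15-px transition band along
the curve with its own rougher speckle (amplitude 0.35, half the
correlation length, plus 4 gray levels of additive noise — doubling that
is the "noisy boundary" condition used in the ablation study); a
background of mean 5, sd 2; optionally a bright pectoral wedge in the
top-left with its own ground truth, and a bright label rectangle in the
background. Everything is quantized to 8 bits and fully determined by the
seed. Ground truth is sampled at 1-px row spacing.

What the phantom does *not* emulate: film-scanner artifacts, the skin
line, anatomical structures (vessels, nipple, glandular patterns), or any
radiometric calibration. Passing tests on phantoms therefore demonstrates
the pipeline's mechanics — learnable boundary texture, seeded
reproducibility, metric behavior — not clinical performance.

## Problem sizes and numerical choices

The shipped studies are deliberately desk-scale. The end-to-end study
trains on 5 phantoms (512²) and traces 5 held-out ones; the ablation study
uses 20 noisy 256² phantoms and a model trained on 5 of the same kind.
Three training-cost choices are the package's own: the hyperparameter grid
search runs on a stratified subsample of at most 500 samples (the grid has
110 points x 5 folds; accuracy estimates on 500 samples separate the grid
plateaus just as well), Platt calibration uses at most 2000 out-of-fold
values, and `train_boundary_model()` anchors positives on every 3rd
ground-truth point — at 1-px spacing adjacent positives are near
duplicates at the 50-px window scale. The final SVM always uses all
samples.

Known limitations, measured on phantoms: the texture model localizes the
boundary to roughly 4 px (mean absolute error of the per-row probability
argmax), because calibrated probabilities saturate near 1 over a ±10 px
plateau around the band and a 50-px window changes only gradually under
small shifts. Traced boundaries land around 5–8 px mean perpendicular
deviation as lateral drift accumulates inside that plateau. The smoothness
and prior factors improve stability and smoothness (the ablation ordering)
but cannot manufacture localization the texture factor does not provide.
Fitting the smoothness Gaussian on coarser-spaced ground truth (10-px
steps, avoiding integer-quantization of slopes) was evaluated and did not
improve end-to-end accuracy; the full-resolution fit is kept.

## Reproducibility

Every stochastic stage (phantom generation, sample collection, fold
assignment, subsampling) takes an explicit integer seed and restores the
caller's RNG state. The tracer itself is deterministic. Model archives are
single JSON files storing the PCA basis, support centers, calibration, and
feature configuration at full numeric precision; a version field guards
against format drift, and tracing refuses a window that differs from the
one the archive was trained with.
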