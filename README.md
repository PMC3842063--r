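# mammotrace

Probabilistic breast-boundary tracing in mammograms.

## What it does, and for whom

Extracting the breast region from a mammogram — separating tissue from
the near-black background, and the pectoral muscle from the breast in
MLO views — is a preprocessing step that most CAD pipelines need and
that intensity thresholds and gradient-driven snakes handle poorly: the
breast boundary is a gradual, textured transition, not an edge.
`mammotrace` implements a sequential probabilistic tracer for that
boundary, aimed at researchers in mammographic image analysis who need a
reproducible, trainable boundary extractor plus the metrics and
baselines to evaluate it.

The boundary is grown point by point from an automatically found seed.
Among the candidate pixels within radius *r* of the current head, the
tracer accepts the one maximizing

P(Tⁱ) · P(P_cⁱ | Pᵏ, Pᵏ⁻¹) · P(P_cⁱ)

* **P(Tⁱ)** — texture probability: a Platt-calibrated RBF-SVM over
  PCA-reduced local binary pattern (LBP) histograms of the 50×50 window
  around the candidate, trained on boundary vs. non-boundary windows.
  LBP here uses the strict threshold (bit set iff neighbor > center),
  and the window histogram is computed per quadrant (4 × 256 bins).
* **P(P_cⁱ | Pᵏ, Pᵏ⁻¹)** — smoothness: a bivariate Gaussian over the
  pair of consecutive segment slope angles `(atan2(Δx, Δy))`, fitted by
  maximum likelihood on training boundaries.
* **P(P_cⁱ)** — a lower-branch Laplace prior `exp(−(μ−x)/β)/(2β)` of
  the texture probability (μ = 1, β = 0.05), which multiplies by *e*
  for every 0.05 of extra texture probability and thereby separates
  candidates whose sigmoid probabilities all sit near 1.

Everything runs without external data: a seeded phantom generator
produces mammogram-like images (noisy dark background, textured
boundary band, bright interior, optional pectoral wedge and label
artifact) with exact ground-truth boundaries, so training, tracing,
evaluation (`acc_mean`, curve measure) and the active-contour /
threshold baselines are all exercisable end to end.

## Worked example

```r
library(mammotrace)

# three training phantoms and one test phantom, fully seeded
train <- lapply(101:103, function(s)
  generate_phantom(phantom_config(size = c(256L, 256L), seed = s)))
test <- generate_phantom(phantom_config(size = c(256L, 256L), seed = 999))

models <- train_boundary_model(train, seed = 1)
models$texture$cv$accuracy
#> [1] 0.992

b <- trace_boundary(test$image, models$texture, models$smoothness,
                    trace_config())
nrow(b); attr(b, "termination")
#> [1] 35
#> [1] "no boundary-classified candidate"

cmp <- compare_boundaries(b, test$gt_boundary)
round(cmp$acc_mean, 2); round(cmp$curve_diff, 1)
#> [1] 8.17
#> [1] 10866
```

The texture SVM separates boundary from non-boundary windows at 0.99
cross-validated accuracy; the traced boundary runs the height of the
phantom with a mean perpendicular deviation of ≈ 8 px from ground truth
(the 50-px descriptor window is proportionally large on a 256² image —
the shipped 512² study averages ≈ 5.6 px). `curve_diff` compares the
smoothness of the two polylines: the traced curve (steps of up to the
search radius) is stretchier than the 1-px-spaced ground truth, which is
expected and is why the ablation study compares modes against each other
rather than against zero.

A command-line front end wrapping these functions (subcommands `synth`,
`train`, `trace`, `evaluate`, `ablate`, `baseline-snake`,
`baseline-threshold`) is installed as `exec/mammotrace`.

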