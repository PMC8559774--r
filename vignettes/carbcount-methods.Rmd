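---
title: "carbcount: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carbcount: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`carbcount` is a desk-scale implementation of an image-based
carbohydrate-counting pipeline: given one annotated RGB image of foods on
a white plate, it segments each detected item, regresses its weight from
projected geometry, and converts weights to macronutrients through a food
composition table. This vignette explains the models behind each stage,
the parameters that matter, and the choices made where the design was
genuinely open.

## The estimation problem

A single photograph fixes neither depth nor scale: the same dish
photographed 10% closer covers ~20% more pixels. The system therefore
leans on two geometric anchors. First, the shooting angle is restricted
to three known values (30°, 60°, 90° from the tabletop), so
foreshortening is a known factor rather than a nuisance parameter.
Second, a tablespoon head of fixed real size may lie on the plate; its
apparent size is the only carrier of the pixels-per-centimeter scale.
The weight regressor is duplicated accordingly: a *spoon-corrected*
variant sees the reference geometry and can undo camera-distance
variation, a *no-spoon* variant cannot and has to fall back on the
typical scale of the training data. The package trains and evaluates
both, and routes each scene to the variant its content supports.

## Synthetic scene generator

No public image corpus with measured weights exists for this task, so
the generator is a first-class module rather than a test fixture. It
emulates the acquisition protocol the pipeline is designed for:

- **Portions on an exchange grid.** Each item's true weight is
  `grams_per_exchange × step` with `step ∈ {0.5, 1, …, 3}`, rounded to
  integer grams — portions grow in half- or whole-exchange increments,
  as a dietitian would plate them.
- **Footprint model.** The deterministic projected area is
  `c · w^(2/3) · sin(θ) · s²`: a mound-like portion's footprint grows
  with the 2/3 power of its volume, an oblique view shrinks it by the
  sine of the elevation, and the pixel scale `s` (image fraction per cm)
  enters squared. The 2/3 exponent and sine foreshortening are our
  modeling choices — a real system learns whatever nonlinearity its data
  carries — and were picked to give the regressor a realistic curved,
  angle-dependent target.
- **Noise.** Item areas get multiplicative lognormal noise (CV 5% by
  default — plating irregularity, mask imperfection), and each scene
  draws its pixel scale from a lognormal around the nominal 0.03
  image-fractions/cm with CV 15% (camera-distance variation). The spoon
  footprint is noise-free by construction so that it carries clean scale
  information; its 6 cm × 4 cm elliptical head is fixed, though real
  tablespoons vary.
- **Layout.** 1–4 items per scene, non-overlapping boxes placed
  uniformly at random (bounded retries, then the scene is redrawn), the
  spoon present with probability 0.8, the angle uniform over the three
  values.

Defaults were chosen once to represent realistic acquisition and are not
tuned per experiment. What the generator does *not* emulate: occlusion,
plate and bowl rims, texture, specularity, shadows, or spoon-shape
variety. Passing tests on this data demonstrate that the pipeline's
*geometry* is sound — that weights are recoverable from areas when the
assumed projection holds — not that the system would survive real
photographs.

The generator's closed-form inverse (`analytic_registry`) doubles as a
reference estimator: with zero noise it recovers every weight exactly
(up to integer rounding), which is what the end-to-end conservation
tests exploit.

## Segmentation

`segment_box` is a fully automatic GrabCut-style loop. The box interior
starts as unknown foreground, everything outside is hard background.
Each region's colors are modeled by a K = 5 full-covariance Gaussian
mixture; segmentation alternates a model refit with a global min-cut of

```
E(labels) = Σ_p −log p(z_p | mixture of label_p)
          + γ Σ_{(p,q) differing} (1/dist) · exp(−β‖z_p − z_q‖²)
```

over 8-neighbor pairs (1/√2 weight on diagonals), with
`β = 1/(2·mean squared neighbor difference)` computed once per image and
γ = 50 — the classic defaults, since the method is cited without
parameters. The cut is solved exactly as an s–t min-cut (igraph's
max-flow); on unknown regions small enough to enumerate, the test suite
checks the cut energy against the exhaustive minimum over all 2ⁿ
labelings.

Numerical choices: covariances are regularized by adding 10⁻⁵·I, which
keeps the energy finite on single-color regions; mixture components are
seeded by k-means with a fixed seed (component count shrinks to the
number of distinct colors when an area is flat); β collapses to 0 on a
perfectly uniform image. The refit step runs warm-started EM on each
label's pixel set and keeps the refit only if it does not lower the data
likelihood — this makes the energy provably non-increasing across
iterations, an invariant the tests assert on every fixture. If the cut
empties the foreground, the full box is returned as the mask and the
result flagged; the pipeline then proceeds with the box area.

## Weight regression

Each food class gets a model pair: dense layers [input, 100, 50, 25, 1],
rectified-linear activations, linear output, squared-error loss, Adam.
The 11-feature input is `[food area, xmin, ymin, xmax, ymax, spoon
area, spoon xmin, ymin, xmax, ymax, angle/90]`; the 6-feature variant
drops the five spoon fields. The feature order and normalization (areas
as image fractions, angle divided by 90) are frozen in the registry file
format. Food area comes from the segmentation mask when one exists and
from the bounding box otherwise (flagged); the spoon contributes its box
area, since only the head is annotated and the constant ellipse-to-box
ratio is absorbed by learning.

Training defaults — none of which are dictated by the problem — are Adam
step 10⁻³, batch 32, at most 500 epochs with early stopping (patience 50
epochs) on a 10% validation slice of the training split, inputs
standardized and the target linearly scaled inside the optimizer
(predictions are returned in grams and clamped at zero, then rounded to
integer grams). Every model's seed derives from the registry seed, so a
registry is bit-reproducible. The 80/20 split is stratified per
(class, angle) cell with at least one test item per cell of five or
more, making the three angles equally represented on both sides.

Per-class models are the default (a global model would have to learn the
class-specific shape coefficient as a latent input); classes with fewer
than 20 training examples are skipped with a warning rather than fitted
badly.

## Pipeline and mock detector

The real system's object detector is trained on a non-public image
corpus, so the pipeline treats detection as a pluggable interface. The
bundled mock detector reads a scene's ground-truth items and corrupts
them per configuration: per-class recall (dropping garnish or meat items
that carry little carbohydrate mirrors the validation behavior such
systems show), multiplicative box jitter, uniform confidences. With
recall 1 and jitter 0 it is an oracle. Detected items missing from the
composition table or the registry are skipped and flagged; an empty
detection set is a valid, flagged, zero-total result. Scene totals are
defined as the exact sum of per-item nutrients, and with the oracle
detector, zero generator noise and the analytic estimator the whole
pipeline is a carbohydrate identity up to the ≤ 0.5 g-per-item cost of
integer rounding.

## Agreement statistics

The validation statistics are implemented with their definitional
denominators and checked against brute-force evaluations to 10⁻¹⁰:
Lin's concordance uses n-denominator moments (the original definition),
Bland–Altman uses the 1.96 factor with differences oriented
estimate − reference, and the Dupont–Plummer paired sample size returns
the smallest `n ≥ (t_{1−α/2,n−1} + t_{power,n−1})²(σ/δ)²`, iterating
from the normal-approximation start and walking back to confirm
minimality. Percent error uses the measured summation as denominator
and is reported to one decimal. Degenerate inputs are handled
explicitly: identical series report perfect agreement with a flag,
constant nonzero differences report p → 0 with a flag, zero-variance
series make Lin's Rc an error rather than a silent NaN.

The comparison-table formatter labels whether estimators' carbohydrate
values were recomputed from converted gram weights or taken as stated —
both conventions appear in practice when human raters answer partly in
exchange units and partly in grams, and the table should say which one
it used.

## Problem sizes and reproducibility

The standard experiment in the tests and the acceptance script uses the
13 bundled carbohydrate-bearing classes, 2,000 scenes (~4,900 items,
~380 per class), and the default noise; per-class training plus
evaluation completes in well under a minute on one CPU. The noiseless
recovery study uses 3 classes at 3,000 scenes, because the
spoon-corrected variant needs on the order of 1,500–2,000 examples per
class before its five distractor reference features stop inflating
held-out error. All randomness — generation, splitting, initialization,
shuffling — funnels through explicit integer seeds.

## Known limitations

- The geometry is idealized: no occlusion ("no food behind other food"
  is an acquisition rule, not a property of real meals), no containers,
  one spoon shape, additive Gaussian pixel noise only.
- The no-spoon variant is structurally scale-blind; under 15% scale
  jitter its errors are several times those of the spoon-corrected
  variant, and scenes without a reference dilute per-class correlation
  between predicted and true weight.
- Segmentation assumes a monotonous background; patterned or reflective
  plates defeat color mixtures, which is documented rather than solved.
- The composition table bundled under `inst/extdata` is synthetic — it
  spans realistic carbohydrate densities (0–80 g/100 g) and exchange
  weights but reproduces no national database's values.
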