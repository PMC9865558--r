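---
title: "Optimizing a light-source spectrum for machine vision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a light-source spectrum for machine vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightspd)
```

## The problem and the observation model

A machine-vision system images a scene under an illuminant mixed from
`NL` sub-lights (LEDs or simulated Gaussian lines) with intensities
`x`. The accumulated SPD is `l(λ) = Σᵢ xᵢ qᵢ(λ)`, and a camera channel
`j` responds with `oⱼ = ∫ cⱼ(λ) l(λ) r(λ) dλ` for pixel reflectance
`r(λ)`. Discretized on a uniform wavelength grid this is `O = CᵀRQx = Ax`
with the per-pixel A-matrix `A = CᵀRQ`. Everything downstream exploits
two consequences of linearity:

* **Render once, relight forever.** Imaging the scene under each
  sub-light yields `A`; the image under *any* mixture is `A x`, so
  illuminant optimization needs no further photography.
* **Differentiability.** `A x` is linear in `x`, so `x` can be a
  trainable layer of a neural network.

Assumptions worth making explicit: the sensor is radiometrically linear
with no saturation or photon noise; illumination geometry (distance,
intensity scale, shading) is ignored, so lighting weights carry an
arbitrary global scale; reflectances lie in `[0, 1]` on the shared grid.
Negative mixture weights are allowed — the resulting "illuminant" is then
a post-capture linear combination of sub-light images rather than a
physical lamp, and `reconstruct_optimal_spd()` flags negative lobes.

### Numerical choices in the model

* The integral is a rectangle-rule sum with `Δλ` equal to the grid step,
  and `Δλ` is folded into `A`. This makes the discrete identity
  `O = Ax` *exact*: rendering through A-matrices and imaging under the
  accumulated SPD agree to machine precision, which the test suite
  asserts at `1e-10` relative over random scenes.
* Resampling (`resample_spectra()`) is linear interpolation, with values
  outside a spectrum's measured band set to 0 rather than extrapolated —
  an SPD vanishes outside the range where it was characterized.
* The D65 reference is packaged as the standard relative SPD (100 at
  560 nm) at 5-nm steps over 300–830 nm, linearly interpolated from the
  canonical 10-nm tabulation. Since D65 only ever serves as a
  least-squares *target*, interpolation detail has no bearing on any
  reported quantity.
* `approximate_illuminant()` uses the Moore–Penrose pseudo-inverse
  (minimum-norm least squares); the tests verify the normal equations
  and Monte-Carlo optimality of the residual.

## The two optimizers

### Alternating linear SVM

The linear decision function `ŷ = sign(wᵀA x + b)` is bilinear in
`(w, x)`. Fixing one variable makes the margin problem in the other an
ordinary linear SVM: the `w`-step trains on rendered features
`oᵢ = Aᵢx`, the `x`-step on transformed features `zᵢ = Aᵢᵀw`. Choices
made where the formulation leaves room:

* **Soft margin.** The hard-margin constraint `yᵢ(wᵀAᵢx + b) ≥ 1` has no
  solution on non-separable data, so both subproblems use hinge-loss
  soft margin with a shared penalty (default `cost = 1`); hard margin is
  recovered as `cost → ∞`. The subproblems are solved by libsvm via
  `e1071::svm()` with a tight termination tolerance (`1e-8`), and the
  `x`-step is independently cross-checked against a generic
  quadratic-programming solution of the dual (`kernlab::ipop`) in the
  tests.
* **The bias `b` is refit in both steps** — it belongs to whichever
  margin problem is currently being solved and costs nothing.
* **Convergence** is declared when the relative change of both `w` and
  `x` falls below `1e-4` (at most 50 sweeps). The per-sweep history
  records both soft-margin objectives and the shared hinge loss.
* **Restarts** draw initial `x` uniformly from `[-1, 1]^NL` (trial `t`'s
  init does not depend on the number of trials, so restart experiments
  nest). The best trial is selected by F1 — on a validation set if one
  is supplied, else on the training data; inside cross-validation the
  selection uses the training folds only, to avoid leakage.
* **Ties at decision value 0 predict class +1**, a fixed documented rule.

### Neural network with a trainable rendering layer

The rendering layer computes `A x` per pixel; an FCL model (1×1 input:
`n_layers` hidden fully connected layers of `n_units`, then a 2-unit
softmax output) or a CNN (5×5 input: two valid 3×3 stride-1 convolutions
with `conv_filters` filters, then `n_layers − 2` hidden FC layers) sits
on top, and `x` and the classifier weights are trained jointly by
backpropagation on softmax cross-entropy. The architecture grid is
layers `{3, 5, 7}` × units `{10, 15, 20}` × activation `{relu, none}`,
with 10 conv filters and dropout 0.3; `grid_search()` scores each of the
18 combinations by k-fold CV F1.

Decisions where the architecture description was genuinely open:

* For the CNN, the layer budget `n_layers` is read as two convolution
  layers plus `n_layers − 2` fully connected ones; with no pooling and
  "valid" 3×3 convolutions a 5×5 patch reduces 5 → 3 → 1 spatially,
  cleanly consuming the patch.
* Dropout (`p = 0.3`) is applied after each hidden fully connected
  layer (placement is otherwise unspecified); conv layers get none.
* Two lighting-weight random init variants exist in the literature this
  follows (`[-1, 1]` and `[0, 1]`); both are implemented
  (`init_lighting()`), with `random_pm1` the default. The other schemes
  are the all-ones vector and the D65 pseudo-inverse weights.
* Inference applies softmax once (it is part of the loss during
  training); the loss is evaluated in log-sum-exp form, so `±1000`
  logits are handled without overflow.
* The optimizer is minibatch Adam (`lr = 1e-3`, 200 epochs, batch 64 by
  default) — these are exposed in `nn_config()` since no canonical
  values exist. Training is bit-deterministic given the config seed
  (weight init, batching and dropout masks all derive from it).

The backward pass is hand-derived (dense layers, im2col convolutions,
and the rendering layer's gradient `∂L/∂xᵢ = Σ ∂L/∂R · A[·,·,i]`); the
test suite checks every gradient path against central finite differences
at `1e-4` relative, and checks that `f(A|x, W)` with explicit rendering
equals `f'(Ax|W)` on pre-rendered input.

## The synthetic task

Real oral/dental spectral databases are not redistributable, so the
package generates its own labeled reflectance cubes
(`make_class_spectra()`, `generate_scene()`):

* all classes share one smooth enamel-like base spectrum (a rising
  sigmoid around 520 nm with a gentle ripple, values ≈ 0.25–0.65);
* each non-base class deviates by a Gaussian bump in its own band
  (default FWHM 50 nm, amplitude 0.15, alternating sign), so classes
  overlap under broadband light but separate under spectral weighting;
* pixels add iid Gaussian reflectance noise, clipped to `[0, 1]`. The
  default `noise_sd = 0.08` emulates the substantial within-class
  variability of tissue reflectance and keeps one-vs-rest F1 in a
  non-saturated range (~0.85–0.98 across methods on the default task)
  rather than at a ceiling of 1.0, so the comparison between optimized
  and fixed lighting is informative.

What the generator does *not* emulate: spatial texture and specular
highlights, class-dependent noise, smooth illumination gradients,
annotation errors, and the 40-class taxonomy of real dental data — only
a handful of spectrally defined classes on a stripe layout (any integer
layout matrix can be supplied). Passing tests therefore demonstrate the
*mechanics* of lighting optimization (rendering correctness, optimizer
behavior, metric orderings), not clinical performance.

Patch datasets follow the central-pixel rule: the one-vs-rest label of a
`p × p` patch is the class of its central pixel; windows that exit the
image are discarded (no padding is invented), and patches straddling
class boundaries are kept. Cross-validation folds are stratified by
label and deterministic given a seed.

## Evaluation choices

* `binary_metrics()` uses `F1 = 2TP/(2TP + FP + FN)` with `F1 = 0` by
  convention when the denominator vanishes.
* The fixed-illuminant baseline freezes `x` at the pseudo-inverse D65
  approximation while the classifier still trains — so the comparison
  isolates the value of *optimizing the light*, not of training at all.
* The Mahalanobis report measures, for every "rest" sample, the squared
  distance from the target class's distribution. The printed form of the
  scatter matrix in the source formulation is uncentered and unscaled;
  because the surrounding prose describes a variance–covariance matrix,
  the default is the standard centered covariance with `1/(Nc − 1)`
  scaling plus a small ridge (`1e-6 · trace/Nd`), and the literal
  uncentered form is available via `centered = FALSE`. The squared
  distance (no square root) is the default output. Distances on held-out
  or full data are the caller's choice; the packaged experiments use all
  labeled samples of the task.
* For 5×5 RGB patches the analysis feature space is the flattened
  rendered patch, `Nd = 75`.

## Scale of the packaged experiments

The packaged experiments and tests run on a 24×24-pixel two-class scene
(576 pixel samples, 400 5×5 patches) with 12 sub-lights on a 400–830 nm
grid at 10-nm steps, 5-fold CV, 5 restarts for the alternating
optimizer, and 150–400 training epochs for the networks. These sizes
were chosen so the full behavioral suite exercises every code path on
ordinary hardware; all of them scale up through the same interfaces.

Two further choices for the small-task measurements deserve a note:

* **Loss-convergence checks** run on a near-noiseless (separable)
  variant of the scene with dropout disabled and `lr = 1e-2`: with only
  10-unit layers, dropout noise bounds the achievable training loss well
  away from zero, and the check targets the optimizer, not the
  regularizer.
* **Concentration of lighting mass.** The learned `|x|` share on the
  sub-lights covering the discriminative band is compared to the uniform
  share (the neutral null). For the network this share is measured from
  the all-ones initialization, whose covering share *equals* the uniform
  share exactly — a random init's share is itself random and would
  confound the measurement. The end-to-end network moves mass toward the
  band only modestly: with enough capacity it can classify well while
  leaving `x` near its initialization, and its learned lighting weights
  vary from run to run. This instability of network-learned lighting
  weights is a known property of the approach, and it is why the
  packaged Mahalanobis comparison evaluates the 75-dim patch features
  under the lighting learned by the *alternating* optimizer, whose
  weights concentrate stably on the band.

## Known limitations

* No radiometric calibration, photon/sensor noise model, or
  exposure/distance effects; lighting weights have an arbitrary global
  scale.
* The alternating optimizer is defined for 1×1 pixel features (its
  classifier is a single linear functional per channel); patch inputs
  belong to the CNN path.
* The alternating scheme has no global convergence guarantee — each
  subproblem is solved exactly, but the pair may cycle near the fixed
  point; the history lets users inspect this.
* Network-learned lighting weights are not unique across seeds or folds;
  multiple trials and per-fold inspection (`cross_validate()` stores
  `learned_x` per fold) are the intended workflow.
* The packaged camera and LED tables are synthetic Gaussian stand-ins
  with the right peak wavelengths, not measured curves; measured data
  drop in via the CSV readers.
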