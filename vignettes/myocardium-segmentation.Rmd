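---
title: "Entropy-weighted local level sets for myocardium segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted local level sets for myocardium segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlv)
```

## The problem

A short-axis black-blood cardiac MR slice shows the left-ventricular blood
pool as a dark, roughly circular region, surrounded by the bright
myocardial annulus and a heterogeneous background (lung, liver, chest
wall, fat). The task is to delineate the endocardial and epicardial
borders automatically; the myocardium is the annulus between them. Two
properties of this data drive the design: both borders are close to
circular, and intensities are corrupted by smooth multiplicative
inhomogeneity (bias fields) plus noise, so a single pair of global region
means — the assumption of the classical two-phase Chan–Vese model — does
not describe either side of the contour well.

## Model

### Global baselines

The global Chan–Vese energy fits one mean to the interior and one to the
exterior of the contour, weighted by λ_in and λ_out, with a length term μ
and an area term ν. `cvStep()`/`runCV()` implement its gradient descent
with the smooth Heaviside

H_ε(t) = ½(1 + (2/π) arctan(t/ε)),  δ_ε(t) = (1/π) ε/(ε² + t²).

The arctan pair is globally supported, so the contour can be attracted by
image structure it does not yet touch; this is the standard choice for
region-based models and is what lets a Hough-initialized circle snap to a
border a few pixels away. The entropy-weighted variant (`model = "ecv"`)
replaces (λ_in, λ_out) by the Shannon entropies of the interior and
exterior intensity histograms, recomputed each iteration. Entropy is low
for a homogeneous region, so the less homogeneous side receives the larger
weight and is corrected faster; the energy settles when the two
homogeneities balance. The diagnostics of `runCV()` record both weights
per iteration, and the test suite checks that on a bimodal image whose
initialization sits inside the homogeneous object the exterior weight
dominates until the two are balanced.

### Local adaptive model

The full model (`runSMLV()`) localizes the fitting energy. Every grid
point in the narrow band |φ| < `bandWidth` carries a square window; within
window j the local interior/exterior means u_j, v_j are Heaviside-weighted
means of the window's intensities, the local weights E_in^j, E_out^j are
the entropies of the window's two sub-regions, and the force density at a
pixel x of the window is δ_ε(φ(x))(E_in^j (I−u_j)² − E_out^j (I−v_j)²).
Contributions of overlapping windows are summed — the image energy is a
sum over band points of per-window energies, so a pixel covered by many
windows legitimately receives many contributions — and the field update is

∂φ/∂t = δ_ε(φ) [ −ν − Σ_j density_j ],

followed by Gaussian smoothing of φ. Smoothing by a kernel of width ξ is
equivalent to evolving φ by its Laplacian, which is why no explicit
curvature term and no re-initialization are needed.

Two readings of the printed gradient were possible: δ applied once
(outside the bracket) or also inside each window density. We apply it in
both places, as printed; the factor δ² concentrates the data force tightly
around the zero level set, which suits the narrow-band design.

The window size is adaptive: starting from half-size `winInit`, a window
grows by one pixel while its intensity-histogram entropy is below
`winEntropyThreshold`, capped at `winMax`. A curve cannot move to minimize
an energy computed over a perfectly homogeneous neighborhood — there is no
boundary information in it — so homogeneous windows grow until they see
structure. Windows that intersect only one sign of φ are skipped for that
iteration.

In the limit of a whole-image window with unit weights, one window's force
density equals the global Chan–Vese data force exactly; the test suite
asserts this to 1e-8, which pins the local model to its global ancestor.

### Dual contours

The endocardial and epicardial level sets are initialized from the Hough
circle pair and evolved independently; afterwards the endocardial mask is
intersected with the epicardial one, and the myocardium is defined as the
exact set difference. Independent evolution keeps the model simple and
makes each contour's diagnostics interpretable; the intersection guarantees
a well-defined annulus even if the two fields cross. A coupled evolution
(e.g. a shared shape prior) is deliberately out of scope.

## Initialization

`detectCircles()` votes edge pixels into a (row, col, radius) accumulator
at integer radius steps. Feature points are pixels whose gradient magnitude
is both in the top `edgeQuantile` fraction (default: top 10 %) and above
20 % of the image's peak gradient. The quantile bounds the feature count
without any intensity normalization; the relative floor exists because a
smooth bias field tilts entire homogeneous regions, and on a biased image
those gentle slopes otherwise flood the top decile — every circle
inscribed in such a region would then collect perfect support. Scores are
normalized by the number of perimeter offsets at each radius so circles of
different radii compete fairly.

Peaks are extracted greedily with non-maximum suppression over a
(radius/2)-px neighborhood in the center plane but only max(2, radius/6) px
along the radius axis. The narrow radial window matters anatomically: the
endocardial radius is typically well within radius/2 of the epicardial
one, and a radially symmetric suppression ball would delete the inner
border's peak as a "duplicate" of the outer one.

`selectLVPair()` searches all ordered (outer, inner) pairs with the inner
radius smaller and the centers within `concentricityTol` (default 10 px),
and keeps the pair with the largest summed score. A single spurious blob
can outscore either true border on a noisy image, but the jointly
best-supported concentric pair is reliably the ventricle. When no
admissible pair exists — the documented failure mode near bright fat or
muscle — the function raises an initialization-failure error rather than
guessing.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| ν | 0.05 | – | area penalty of the local model; small because the data term dominates |
| Δt | 0.05 | – | explicit Euler step; low because overlapping windows sum |
| ξ | 1.0 | px | Gaussian width; must exceed √Δt so smoothing dominates roughening |
| ε | 1.5 | px | Heaviside/Dirac width |
| bandWidth | 3 | px | narrow band |φ| < b carrying local windows; ≥ ε |
| winInit / winMax | 4 / (H+W)/16 | px | window half-size range; the cap reuses the optimal fixed-window size of the fixed-window comparator |
| winEntropyThreshold | 0.5 | nats | windows grow until this entropy; ≈ a 75/25 two-level split |
| nBins | 32 | – | histogram bins over [0, 255] |
| weightFloor | 0.05 | nats | keeps a perfectly homogeneous region from zeroing its term |
| tol / tolWindow | 1e-4 / 5 | – | stopping: relative change of ΣH_ε(φ) small for 5 consecutive iterations |

Entropies use the natural logarithm (nats); only the scale of the weights
depends on this choice, and they enter the update as a balance between two
terms. Intensities are canonicalized to [0, 255] at load time
(`loadImage()`), the range all squared-intensity parameter scalings
presume; a constant image maps to zeros. The global baselines default to
the high-contrast synthetic setting (μ = 0.01·255², ν = 0, unit λ); the
published per-patient rows (μ = 0.5·255², ν = 0.2) are available as
`cvTable1Preset()`.

## Numerical choices

* **Per-step update cap.** Squared residuals on the [0, 255] scale produce
  forces orders of magnitude above the level-set scale; an uncapped
  explicit step flips boundary pixels bang-bang and the contour enters a
  pixel-scale limit cycle instead of settling. Both `smlvStep()` and
  `cvStep()` therefore cap each pixel's update at one level-set unit per
  iteration — a CFL-style limiter: saturated pixels still move at about a
  pixel per iteration on a signed-distance field, while near equilibrium
  the dynamics are proportional and converge cleanly.
* **Field clipping.** After each local-model step φ is clipped to
  ±3·bandWidth. Clipping never changes a pixel's sign (so it never moves
  the contour) but keeps the interface profile bounded, so the Dirac
  support and the narrow band cannot be starved by runaway amplitudes.
* **Curvature.** div(∇φ/|∇φ|) uses central differences with the gradient
  magnitude floored at 1e-8 (flat fields would otherwise divide by zero).
* **Gaussian smoothing** is a separable discrete kernel truncated at 4ξ,
  normalized to sum 1, with replicate padding: constants are preserved
  exactly, interior linear ramps to rounding error, and the Dirichlet
  energy of any non-constant field strictly decreases.
* **Degenerate inputs.** Empty regions raise empty-region errors; a level
  set with a single sign raises a contour-collapse error (with the
  iteration index when inside a run); non-finite updates raise a
  numeric-instability error. `maxIters = 0` returns the initial field
  untouched.
* **Iteration-count comparisons.** The entropy-weighted versus plain
  global comparison is meaningful only in the proportional regime, where
  the fitting weights modulate the front speed; with updates saturating
  the limiter, both models move at the cap and tie. The packaged
  experiment (acceptance script and tests) therefore runs both models at
  Δt = 2e-4 on 96×96 bimodal images, which puts convergence in the
  hundreds of iterations and resolves the ordering; both models share the
  stopping rule.

## The phantom, and what passing it means

`makeLVPhantom()` renders the geometry and contrast of a black-blood
slice: a dark blood-pool disk (intensity 30), a bright myocardial annulus
(150, radii 16 → 26 px at 128×128, about right for a mid-ventricular slice
at 1.56 mm/px), a mid-gray background (80), optional bright distractor
blobs (200) kept clear of the epicardial disk, a linear multiplicative
bias field across columns, and additive Gaussian noise, clipped to
[0, 255]. Ground-truth masks come from the analytic geometry and are
untouched by the corruptions; output is bit-reproducible per seed.

The phantom deliberately omits much of real data: partial-volume borders
(its edges are one pixel sharp), Rician noise statistics, coil-sensitivity
bias shapes beyond a linear ramp, papillary muscles inside the blood pool,
through-plane effects, and neighboring structures that touch the
epicardium. Passing the phantom tests therefore demonstrates the
*mechanics* of the method — initialization, convergence, robustness
ordering versus the global baseline under bias and noise, insensitivity to
a 3 px initialization shift — not clinical accuracy. The published
patient-level figures depend on data that is not distributable and are not
reproduced here.

Problem sizes throughout the tests and the acceptance script: 128×128
phantoms for the pipeline conditions, 96×96 for the iteration-count and
circle-recovery studies — small enough to iterate on, large enough that
the annulus is several windows thick.

## Limitations

* Circular initialization assumes a roughly mid-ventricular short-axis
  slice; strongly non-circular ventricles (apex, some pathologies) can
  defeat the Hough stage. Bright structures adjacent to the ventricle can
  leave no admissible circle pair; this surfaces as an explicit
  initialization failure.
* The two contours do not interact during evolution; nesting is enforced
  only afterwards.
* Histogram entropies with 32 bins need a few hundred pixels per region to
  be stable; very small windows lean on the weight floor.
* Only single 2-D slices are handled — no multi-slice, 4-D, DICOM or
  NIfTI support.
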