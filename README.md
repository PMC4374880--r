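# smlv — automatic myocardium segmentation by entropy-weighted local level sets

`smlv` segments the left-ventricular myocardium in 2-D short-axis
black-blood cardiac MR slices: the dark blood pool, the bright myocardial
annulus around it, and heterogeneous surroundings. It is aimed at
researchers who need a fully automatic, reproducible delineation of the
endocardial and epicardial borders — for example as the first step of
myocardial T2* analysis — together with the standard evaluation metrics and
a synthetic phantom generator for controlled benchmarking.

## Method

The pipeline has three stages.

**1. Circular Hough initialization.** Both ventricular borders are close to
circular in a short-axis slice. Edge pixels (top gradient quantile, with a
relative floor that rejects smooth shading) vote for every consistent
(center, radius) pair; accumulator peaks are extracted with non-maximum
suppression, and the admissible concentric pair with the best total
perimeter-normalized support becomes the epicardial/endocardial
initialization. Each circle seeds a signed-distance level-set field
φ = R − ‖z − c‖, positive inside.

**2. Level-set evolution.** Each contour evolves under a region-based
fitting energy of Chan–Vese type, with three modifications:

* *Entropy weighting.* The interior/exterior fitting weights λ_in, λ_out
  are replaced by the Shannon entropies E_in, E_out of the two regions'
  intensity histograms (recomputed every iteration), so the less
  homogeneous side is penalized harder and no per-image λ tuning is needed.
* *Adaptive local windows.* For every point of the narrow band |φ| < b, a
  square window grows from half-size 4 until its intensity entropy exceeds
  0.5 nats (capped at (H+W)/16). Within each window the force density is

  δ(φ(x)) ( E_in^j (I(x) − u_j)² − E_out^j (I(x) − v_j)² ),

  where u_j, v_j are the Heaviside-weighted local means and E^j are the
  window's own sub-region entropies; overlapping windows sum. The total
  update is ∂φ/∂t = δ(φ)[−ν − Σ_j (·)], with a small area penalty
  ν = 0.05.
* *Gaussian regularization.* After each Euler step, φ is convolved with a
  Gaussian of width ξ > √Δt. This replaces both the curvature (length)
  term and re-initialization.

With the window spanning the whole image and unit weights the force reduces
exactly to the global Chan–Vese data force; the global model and its
entropy-weighted variant are included as baselines (`runCV`), along with a
fixed-window comparator (`ncvConfig`, window (H+W)/16, unit weights).

**3. Masks and metrics.** Thresholding φ > 0 gives the endocardial and
epicardial masks; the myocardium is exactly their set difference
(nesting enforced). Evaluation uses the Dice coefficient, the
misclassification error, and the Hausdorff distance between 4-adjacency
contours.

## Worked example

Segment a stressed synthetic phantom (±40 % linear bias field, Gaussian
noise σ = 10) and score the result against the known truth:

```r
library(smlv)
ph  <- makeLVPhantom(phantomSpec(biasAmplitude = 0.4, noiseSigma = 10, seed = 1L))
res <- segmentMyocardium(ph$image)
initCircles(res)
#> LVCircleInit
#>   epicardial:  center (63.0, 63.0) r=26.0 votes=0.865
#>   endocardial: center (64.0, 63.0) r=16.0 votes=0.898
res
#> SegmentationResult 128x128
#>   endo: 793 px (29 iters); epi: 2126 px (20 iters); myocardium: 1333 px
round(evaluateMasks(myoMask(res), ph$myo_mask), 4)
#>   dice     me     hd
#> 0.9921 0.0013 1.0000
```

The detected circles sit within a pixel of the true borders (radii 16 and
26 px); after 20–30 iterations per contour the myocardial annulus overlaps
the ground truth with Dice 0.992, misclassifies 0.13 % of pixels, and its
contour never strays more than 1 px from the true border.

A command-line front end ships in `inst/exec/smlv-cli.R`
(`segment`, `evaluate`, `phantom`, `compare`, `init-preview`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/smlv-cli.R", package="smlv"))')" \
    segment slice.png --out results/
```

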