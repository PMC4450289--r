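---
title: "Vein segmentation by window-wise quadratic smoothing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vein segmentation by window-wise quadratic smoothing: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinseg)
```

## The problem and the model

In transillumination (infrared) finger images, haemoglobin absorbs the
light, so veins appear as dark ridged valleys on bright tissue. Scattering
blurs them into roughly Gaussian cross-profiles, which makes direct
second-derivative detection noisy. `veinseg` instead estimates a smooth
surrogate $u$ of the observed image $u_0$ by minimizing a quadratic
(edge-free, Mumford–Shah-like) objective

$$J(u) = \tfrac12 \sum \lVert \nabla u \rVert^2
       + \tfrac{\lambda}{2} \sum (u - u_0)^2,$$

and reads the veins off the *nonsmooth residual* $u - u_0$: smoothing
raises concave valley minima, so the residual is positive exactly where
the intensity surface curves upward — vein cross-sections — and near zero
on smooth tissue.

Two simplifications make this fast enough to run per pixel:

1. **Separability.** The two directional smoothness terms are minimized
   independently. Each 1D problem has the stationarity condition
   $(\lambda + 2)u_x - u_{x-1} - u_{x+1} = \lambda u_{0,x}$, a symmetric
   tridiagonal system ($\lambda + 2$ diagonal, $-1$ off-diagonals) that is
   strictly diagonally dominant, hence positive definite and uniquely
   solvable for every $\lambda > 0$ — the package asserts this
   numerically up to the largest window size it uses instead of carrying
   a formal proof. The joint two-direction system (diagonal
   $\lambda + 4$) is retained only as a small-instance reference
   (`build_grid_system()`); the separable solution is an approximation of
   its minimizer, and a test quantifies (without asserting away) the gap.
2. **Windowing.** The solve is restricted to an $M \times M$ sliding
   window. The operator $B = \lambda A^{-1} - I$ maps a window's pixels
   straight to its residual and is precomputed once, so all per-window
   work is small matrix products. With the default $M = 9$ the system is
   $81 \times 81$.

Boundary rows of each line system keep the full $\lambda + 2$ diagonal.
This corresponds to ghost zeros beyond the window ends (a zero-Dirichlet
closure) rather than a Neumann correction ($\lambda + 1$); the windowed
objective our closed form minimizes therefore includes those two ghost
difference terms. The test-suite oracle minimizes exactly that objective
with a generic numerical optimizer and agrees to below $10^{-6}$.

### Sliding accumulation and padding

Residuals from all window placements are summed into an accumulator
(`residual_map()`). The image is replicate-padded by $M - 1$ on each side
first, and the central $N \times N$ part of the accumulator is returned,
so every output pixel receives the full $M^2$ placements. We initially
accumulated valid placements only (no padding); that leaves pixels near
the border with partial sums whose ramp is several times larger than a
typical vein response (for a constant image at level 0.5 and $M = 9$,
interior $-5.56$ against $-0.62$ at the border) and it dominated both the
min-max normalization and the threshold statistics. With padding a
constant image produces a constant residual, which the later rescale
removes entirely.

Because the operator is block-diagonal with identical blocks acting on
window rows, the vertical accumulation collapses to a per-row
multiplicity count; the default `"fast"` path exploits this and the
literal `"per_window"` loop is kept as a cross-checked reference (they
agree to floating-point roundoff, tested at $10^{-9}$).

The enhanced image is the sum of the two directional residual fields
(0° and the back-rotated 90° pass), each min-max normalized to $[0, 1]$
first, then normalized again. "Normalization" before the addition is not
defined more precisely by the method's description; min-max is the
weakest assumption that makes the two components commensurate. A
degenerate (constant) component is set to zero. The 90° component is
normalized *after* back-rotation; since min-max rescaling commutes with
rotation, the order only matters for the degenerate case.

## Stage parameters

| Parameter | Default | Meaning |
|---|---|---|
| `norm_window` | 15 px | box side for local mean/sd normalization |
| `eps` | 1e-6 | stabilizer added to the local sd (flat regions) |
| `M` | 9 px | smoothing window side (81×81 system) |
| `lambda` | 1 | data-fidelity weight; validated range 0.1–1 |
| `levels` | 256 | gray levels for co-occurrence thresholding |
| `Y` | 5 px | horizontal line dilation length |
| `majority_max_iter` | 100 | cap for the iterated majority filter |

Local normalization computes the pixelwise z-score against the box mean
and population standard deviation (replicate padding), then min-max
rescales to $[0, 1]$; a constant image maps to all 0.5. The z-score field
is invariant under global affine intensity changes, which is the point:
shading and illumination gradients are removed before enhancement.
`lambda` trades smoothness against fidelity; the benchmark sweep
(`lambda_sensitivity()`) shows the final evaluation rates move by well
under one percentage point across $[0.1, 1]$, so it is left at 1.

## Thresholding

The enhanced image is quantized to `levels` gray levels and the
co-occurrence matrix of right- and below-neighbor transitions is built
(asymmetric, no transpose added). For a candidate threshold $t$ the two
within-class quadrants (both levels $\le t$; both levels $> t$) are each
normalized by their own mass, and $t^\*$ maximizes the sum of their
Shannon entropies (base 2, $0\log 0 := 0$, ties to the smallest $t$).
Unlike a histogram criterion this is sensitive to spatial arrangement:
two images with identical histograms but different layouts give
different entropy curves, which the tests construct explicitly.

The precise variant — within-quadrant (not global) normalization and the
exclusion of the two cross-class quadrants — is a reconstruction of the
second-order local entropy criterion as used in vessel segmentation
practice; it is isolated in `quadrant_entropies()`/`select_threshold()`
so an alternative variant can be swapped in. One consequence worth
knowing: on a degenerate two-valued image, any split *between* the values
leaves single-cell quadrants with zero entropy, so the criterion prefers
a threshold that lumps the occupied cells into one quadrant. On realistic
many-level enhanced images this does not arise, but on near-binary inputs
the selected threshold can sit outside the two modes, and on dense
samples (vein cover above roughly a quarter of the frame) we have
observed the global maximum flip between two competing local maxima,
taking the segmentation from accurate to strongly over-inclusive. This
brittleness is a property of the criterion, not of its implementation;
`threshold_override` exists partly for such cases.

Vein pixels carry high residual values, so levels strictly above $t^\*$
are labeled vein. Postprocessing dilates with a centered $1 \times Y$
horizontal element (veins run predominantly along the finger) and then
iterates the 3×3 majority filter (five-of-nine, center counted, zero
padding outside the border — both conventions chosen here; the border
choice is conservative, shrinking toward background at the frame edge)
until the mask stops changing.

## The synthetic database

No real infrared finger database is publicly available, so evaluation
uses a generator (`gen_database()`) that emulates the structure of such
images; its defaults *are* the study conditions for the package's
benchmark numbers and were fixed before those numbers were read off:

* **Frame**: 87 × 212 px — the reference finger-frame geometry of the
  template matcher, so the displacement allowances (57, 38) apply
  unscaled.
* **Vein network**: 2 principal paths seeded at the left edge at heights
  uniform over the central 70% of the frame, random-walking across with
  persistent drift; each step spawns a branch with probability 0.005.
  Branches take a width no larger than their parent's and fade within
  10–40% of the frame width; principal veins cross the whole frame.
  Strokes are disks of half-width 2–5 px stamped along the path, giving
  4–10 px vein diameters — about right for 1–2 mm veins on a finger at
  this resolution — and vein cover around 0.15–0.25 of the frame.
* **Rendering**: veins dark on light, blurred by 3 passes of a Gaussian
  of sigma 1.5 (the scattering halo with its Gaussian-like cross
  profile).
* **Background**: uniform noise in [0.3, 0.9] smoothed 10 times with a
  31-px Gaussian kernel — a smooth nonuniform illumination field. The
  original construction low-pass filtered a *real* infrared image; none
  being available, smoothed noise stands in, and it is smoother and less
  textured than real tissue background.
* **Composition**: weighted sum with vein weight 0.6, clipped to [0, 1].
  Optional distortions: additive Gaussian, salt-and-pepper, or speckle
  noise at a configurable level (none by default).

Reproducibility is part of the contract: every sample derives its seed
from the master seed, and the test suite freezes an MD5 fingerprint of a
small reference manifest, so any change to the generator is a deliberate,
visible act.

What passing benchmarks on these images does **not** show: robustness to
real tissue texture, specular artifacts, or acquisition noise — the
background here is smoother than reality, the vein profiles are exactly
Gaussian-ish by construction, and ground truth is the pre-blur stroke
mask rather than a human annotation of the rendered image.

## Evaluation and matching

Pixelwise confusion counts treat vein as the positive class;
sensitivity, specificity and accuracy follow the usual definitions, and
ROC curves sweep the binarization threshold with the morphological
cleanup either applied per point (default, matching the pipeline) or
skipped. On the 20-image reference database (master seed 42) the default
pipeline's mean rates and the lambda sweep are recomputed from scratch by
`scripts/acceptance.R`; the suite's database-level tests use the same
regenerated database. All database-level runs in the tests and the
acceptance script use the 87 × 212 frame and complete in seconds per
image on one CPU.

Template matching slides the central template region of the registered
mask (rows $c_h \ldots h - c_h - 1$, columns $c_w \ldots w - c_w - 1$)
over all $2c_w \times 2c_h$ displacements of the input, counts label
disagreements, and takes the minimum $N_m$ (ties to the smallest
$(t, s)$). The mismatch ratio divides $N_m$ by the vein totals of the two
compared regions: the input's veins inside the best-shift window plus the
template's veins. The printed source formulas for the disagreement
indicator and the ratio are typographically corrupted; both are
implemented from their prose descriptions (indicator: labels differ;
ratio: division by the vein totals), and the input-side term uses the
best-shift window, which is what the displaced indices in the ratio's
sum indicate. A veinless pair yields ratio 0 by convention when the
mismatch count is also 0.

One known divergence from the reference results: on this generator the
per-image segmentation is cleaner than the original study's (accuracy
around 0.94 on most samples), and the mismatch ratio — which is
approximately the in-window error rate divided by twice the in-window
vein density — comes out near 10% rather than ~25%. Reproducing the
larger ratio would require a harder database (notably a textured real
background), not a different matcher.

## Degenerate inputs and numerical conventions

* Rectangles and displacements are 0-based, half-open, row-major.
* Min-max rescales map a constant field to 0 (enhancement components) or
  0.5 (normalized image); an empty co-occurrence quadrant has entropy 0;
  a single-level image selects threshold 0 with a warning.
* ROI auto-detection cuts rows/columns whose near-extreme fraction
  (below 10 or above 245 of 255) exceeds 0.5 and keeps the longest
  surviving run, ties toward the center; it errors rather than return an
  empty crop. It is a stand-in for the original histogram-based finger
  localization, whose exact masks were never published; an explicit
  rectangle can be passed instead, and the pipeline also runs ROI-free.
* The segmentation path contains no randomness; repeated runs are
  bit-identical given the same configuration.

## Limitations

* The entropy criterion's near-tie flips on dense vein cover (above) are
  the main failure mode observed; everything downstream is deterministic
  cleanup.
* The ROI stand-in is heuristic and untested against real acquisition
  shading beyond synthetic margins.
* BMP input is not supported (PNG and PGM are); images are 8-bit
  grayscale only.
* The window size `M` couples to image resolution: veins much wider than
  `M` respond at their edges rather than their cores. At the default
  scale (4–10 px veins, `M = 9`) this does not bind.
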