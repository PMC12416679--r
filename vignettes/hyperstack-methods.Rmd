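---
title: "Methods: focus stacking, calibration and resolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focus stacking, calibration and resolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperstack)
```

This vignette is the package's account of its science: the models each
stage implements, the assumptions behind them, the defaults and why they
were chosen, what the synthetic generator does and does not emulate, and
the numerical decisions that were genuinely open.

## Why focus stacking

A non-contact dermoscope images skin from a working distance of roughly
45 cm. At the magnification needed to resolve ~30 µm features, the depth
of field is far smaller than the relief of curved skin, so any single
frame is sharp only in a band around its focal plane. The acquisition
therefore sweeps the focal plane across an interval around the estimated
subject distance and captures a stack of `n` frames — typically 10 to 20,
enough that every surface point is near focus in at least one frame —
which the software fuses into one all-in-focus (*hyperfocus*) image.

The focal geometry is the thin lens equation `1/f = 1/U + 1/V` relating
focal length, object distance and image distance; `solve_thin_lens()`
fills in any missing conjugate and `plan_focus_sweep()` lays out the `n`
focal-plane distances evenly over `estimate ± half_range` (default
half-range 2 cm).

## Pipeline stages and their models

Stage order is fixed: denoise → color-calibrate → align → focus measure →
fuse. Denoising runs first so that noise is not amplified or warped by the
later stages.

### Non-local means denoising

Each output pixel is a convex combination of pixels `q` in its
`search_window` (default 21 px), weighted by the similarity of the
`comparison_window` patches (default 5 px) around them:

$$w(p,q) \propto \exp\!\left(-\frac{\max(d^2_{pq} - 2\hat\sigma^2,\,0)}{h^2}\right)$$

with `d²` the mean squared patch difference, `h` the
`degree_of_smoothing` (intensity units, default 0.05), and `σ̂` a robust
per-channel noise estimate (1.4826 × median absolute deviation of the
residual against a 3×3 box mean). Subtracting `2σ̂²` removes the noise
floor of the patch distance, the standard correction that keeps weights
from collapsing at realistic noise levels. Borders are symmetric-padded;
channels are processed independently (a deliberate simplification that
keeps the brute-force oracle in the test suite exact). Weights are
nonnegative and normalized, so the filter can never leave the input's
value range and fixes constant images exactly.

### Color calibration

Calibration maps *measured* chart colors to the chart's *reference*
values. The 24-patch reference table ships with the package
(`colorchecker_srgb()`); distances are plain Euclidean metrics in RGB
(0–255) and in CIELab (D65, 2° observer), the latter because Euclidean
Lab distance approximates perceived color difference. Three families are
implemented:

* `linear` — affine least squares;
* `poly2` / `poly3` — least squares on the full multivariate monomial
  basis of total degree 2 / 3 *including all cross terms* (10 / 20 terms).
  "Cubic terms" could also mean per-channel polynomials; the full basis
  strictly contains that model and degrades gracefully, so it is the
  default reading;
* `kmeans2`–`kmeans4` — measured colors are clustered (k-means++ seeding,
  50 restarts, fixed seed) and each cluster gets its own affine map;
  clusters with fewer than 4 members fall back to the global affine map,
  and at application time a pixel uses the map of its nearest centroid.
  This is one consistent reading of using cluster centroids to "adjust"
  the calibration; the piecewise map is discontinuous at cluster
  boundaries, which is why dark-region artifacts can appear with k = 2 —
  documented behavior, not asserted correctness.

Fitting is always in RGB (the chart's native space, scaled to [0,1] for
conditioning); CIELab is an evaluation space only. `evaluate_calibration()`
reports mean RGB and Lab distances per method plus the percentage
reduction against the uncalibrated measurement, sorted best-first by Lab.
On a noiseless polynomial distortion of degree ≤ 3 the `poly3` fit is an
interpolation problem (24 patches ≥ 20 coefficients) and recovers the map
to numerical precision; on the package's cubic-distortion fixture the
ranking poly3 < poly2 < linear in mean Lab distance is a tested
invariant.

### ECC alignment

Frames are registered by maximizing the enhanced correlation coefficient —
the zero-mean normalized correlation between the reference and the warped
moving image — over a translation, euclidean or affine warp, with a
forward-additive Gauss–Newton update and a coarse-to-fine pyramid
(2× block-mean downsampling until the coarsest level is near 32 px). The
objective is invariant to affine intensity changes, which is exactly what
a focal sweep produces (slight exposure/contrast drift between frames).
Both images are zero-meaned inside the valid-overlap mask; the printed
form of the error norm omits the centering, but uncentered correlation is
not illumination-invariant, so the implementation centers.

The stack's reference frame is the one with the smallest focal-plane
distance — at fixed image distance that is the most magnified frame, so
all other frames are only ever magnified *toward* it, never shrunk past
it. When focal-plane metadata is missing, the frame with the largest mean
gradient stands in. Frames are solved outward from the reference, each
initialized from its nearest already-solved neighbor; magnification
varies smoothly along the sweep, so this warm start keeps every solve in
the convergence basin. A frame that exhausts its iteration budget is
flagged and excluded from fusion rather than fused unwarped (a blurred
ghost is worse than one missing frame).

### Focus measure and fusion

Sharpness is the local variance (window 9×9, symmetric padding) of the
Laplacian-filtered luminance (Rec. 709 weights; 3×3 kernel
`[[0,1,0],[1,−4,1],[0,1,0]]`). The kernel and window are the common
defaults of the focus-measure literature — the method itself does not
prescribe them — and both are exposed as parameters. Constant regions
score exactly zero.

Fusion is the literal weighted sum: per pixel, frame `i` contributes
`fm_i / Σ_j fm_j`, the same luminance-derived weight for all three
channels. Where all focus measures vanish (featureless regions) the
weights fall back to uniform `1/k`, so the weights are a partition of
unity everywhere and the fused value is always a per-pixel convex
combination of the frames — it can never leave their envelope. An
optional sharpening exponent on `fm` exists but defaults to 1: fidelity
to the stated fusion rule first.

One consequence of literal linear weighting is worth knowing: partially
defocused frames always retain some weight, so the fused image is very
slightly softer than the per-pixel best frame unless the out-of-focus
frames are strongly blurred. The all-in-focus *ratio* test in the suite
therefore uses a strongly defocused flat-scene fixture, while the
ramp-scene acceptance property (fused focus ≥ per-pixel median on ≥ 95%
of pixels, fused focus map spatially no more variable than the inputs')
runs under the generator defaults.

## Fusion-quality metrics

The four metric families are implemented as faithful, fully parameterized
simplifications; every free parameter is fixed in `metric_params_default()`
and echoed in the report digest, because the exact literature variants the
validation practice refers to are not recoverable and reproducibility
within this package is the goal. Orientations are normalized: `nmi` and
`yang_ssim` are higher-better (1 = perfect), `sf_error` is 0 at ideal and
negative for detail loss, `chen_varshney` is an error (0 = perfect).

* **Normalized mutual information** — 256-bin histograms; MI(fused, frame)
  normalized by half the sum of the marginal entropies, averaged over
  frames. Constant images have zero entropy; the degenerate score is 1
  only for two equal constants.
* **Spatial-frequency error** — RMS first differences in four directions
  (diagonals weighted 1/√2); the reference is assembled from the per-pixel
  *maximum* absolute directional differences over the stack — the gradient
  content an ideal all-in-focus image could attain.
* **Yang's SSIM** — per pixel the two locally most informative (highest
  local variance) frames are chosen; where they are complementary (their
  mutual local SSIM < 0.75) the better fused-to-frame SSIM is taken,
  otherwise the variance-weighted average. Window 7, K1 = 0.01,
  K2 = 0.03.
* **Chen–Varshney index** — 16×16 regions; per region each frame's
  saliency is its summed squared Sobel response, the fused-to-frame
  squared difference is low-pass filtered by a Gaussian
  contrast-sensitivity surrogate (σ = 2 px), and errors are combined with
  saliency weights within regions and across them.

A subtlety the test suite documents: against a stack whose frames are
themselves partly defocused, full-reference scores are maximized *near*
but not *at* the all-sharp mosaic — an infinitesimal blur of the fused
image moves it toward the blurred halves of the inputs and can improve
nmi/yang/cv by a hair (squared-error convexity). Monotone degradation
under blur is therefore asserted from σ = 0.5 px upward; the
perfect-fusion limits (identical frames, fused equal to them:
1 / 0 / 1 / 0) are exact and asserted separately.

## Objective USAF 1951 analysis

Element `e` of group `g` has spatial frequency `2^(g+(e−1)/6)` line
pairs/mm (line width `500/lp` µm; group 4 element 2 → 27.84 ≈ 28 µm). The
analyzer samples the intensity profile across the three bars (bilinear,
0.25 px steps, grayscale first), smooths it with a Savitzky–Golay filter
(polyorder 2; window ≈ half the samples per line width, odd, floored at
5 — the window must scale with bar sampling or fine bars are flattened),
detects extrema with a prominence of at least 5% of the profile's dynamic
range, and declares the element resolved when three minima, each below
80% of the profile's own maximum, alternate with detected maxima in a
min–max–min–max–min pattern. Both the prominence fraction and the 80%
threshold are relative to the profile's own statistics, which makes the
criterion invariant to affine intensity rescaling — a tested property.
The finest resolved element is reported as the strict "last before the
first failure" cutoff *and* as the full resolved set, because with noise
a finer element can occasionally pass after a coarser one fails and the
method does not specify a tie-break; reporting both avoids guessing.

The user-drawn probe lines of the interactive procedure are replaced by
segment specs (CSV/JSON or straight from the synthetic renderer), making
the analysis fully scriptable; the judgment logic is unchanged.

## The synthetic generator

The generator exists so that every stage has inputs with the right
*structure*: it emulates defocus with an isotropic Gaussian PSF whose
sigma is `blur_scale · |1/U_i − 1/z|` (a differentiable surrogate for the
thin-lens circle of confusion — the true PSF of the instrument is not
specified), spatially varying blur via 16 quantized depth layers
composited in scatter form (each layer spreads its own masked light, so
total intensity is conserved; mild weight banding at layer boundaries is
second-order), per-frame magnification drift `1 + drift·(U_i −
median(sweep))` about the image center, and the three sensor noise
mechanisms in physical order — Poisson shot noise, Gaussian read noise,
then a fixed-pattern gain field that depends only on its own seed —
with clipping last. All generators are pure functions of their seeds.

Defaults are the study conditions and were chosen once: working distance
0.45 m, half-range 0.02 m, 10–20 frames, `blur_scale = 80` px·m. The last
value makes the sweep self-consistent: the per-plane depth of field is
comparable to the plane spacing of a 10–20-frame sweep (every scene depth
is sharp in about one frame, strongly blurred at the sweep ends, σ ≈ 8 px)
— the same design logic that fixes the real stack size. Scenes are
skin-toned band-limited speckle with dark lesion-like blobs so focus
measures are informative everywhere; depth models are `flat`, `ramp`
(monotone along rows) and `bump`.

What the generator does **not** emulate: radiometric skin optics
(chromophores, polarization), lens aberrations and field curvature,
occlusion at depth discontinuities, rolling shutter, and realistic
patient-motion statistics (translation jitter is available as a parameter
but its magnitude is not calibrated to anything). Passing tests on
synthetic stacks therefore demonstrates algorithmic correctness — the
stages compute what their models say — not end-to-end performance on real
acquisitions.

## Numerical choices

* Intensities are floating point in [0,1] throughout; files are 8-bit PNG
  or 16-bit TIFF containers (typical camera data is 12-bit, which 16-bit
  holds losslessly). Writes pre-quantize to the container's levels, so
  save/load round trips are exact at both depths.
* Coordinates are (x, y) = (column, row), 1-based at pixel centers, shared
  by every module; warps use bilinear interpolation with border
  replication.
* Convolutions and box filters are exact shift-and-add / summed-area
  implementations with symmetric padding (circular only where energy
  conservation matters, in the renderer's periodic fixtures), chosen so
  that brute-force oracles can match them to 1e-12.
* ECC stops when the parameter update falls below `epsilon` (1e-6) or the
  correlation reaches 1; a non-positive denominator in the update (the
  correlation cannot be improved along the model) stops with the best
  parameters so far and `converged = FALSE`.
* k-means uses k-means++ initialization with a fixed seed and 50
  restarts, then Lloyd iterations; ties in nearest-centroid assignment
  break toward the first centroid.
* The diopter↔distance mapping of a tunable lens is hardware-specific and
  is abstracted as a user-supplied monotone mapping (identity by
  default); `frame_meta` carries `lens_power` for provenance only.

## Problem sizes

Tests and the acceptance script run on 7×7–96×96 rasters, stacks of 3–10
frames, 24-patch charts and two-group targets; these sizes give every
statistical check comfortable margins (e.g. the Poisson-variance check
uses 10⁶ pixels) while the whole suite completes in well under a minute
on one core. Users processing camera-resolution stacks should expect the
ECC and NLM stages to dominate runtime, both scaling linearly in pixel
count (NLM also quadratically in the search window).

## Known limitations

* The k-means calibration's piecewise map is discontinuous; smooth
  cluster blending would remove boundary artifacts at the cost of leaving
  the stated model.
* Linear focus-weighted fusion slightly softens the result relative to a
  winner-take-all rule; the weight exponent parameter allows sharpening
  but defaults to the literal rule.
* The fusion metrics are this package's fixed parameterizations of the
  four families; scores are comparable within this package, not across
  the literature's many variants.
* The configuration file format is YAML; every under-specified parameter
  above has its default recorded in one place (`pipeline_config()`), so a
  run manifest plus a config file fully determines a result.
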