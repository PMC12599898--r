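---
title: "Thick-slice CT simulation: model, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thick-slice CT simulation: model, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsim)
```

## The model

A reconstructed CT slice is not a point sample of the patient along z. The
signal at slice center $p$ mixes tissue over an axial neighbourhood whose
weighting — the slice sensitivity profile — is peaked at $p$ and falls off
with distance, a consequence of how helical reconstruction weights
projections by their axial offset. `ctsim` models this profile as a
triangle of half-width equal to the slice thickness $t$:

$$g(p, l, t) = \max\!\left(0,\; 1 - \frac{|p - l|}{t}\right),$$

and simulates a thick slice at $p$ from a stack of thin slices at positions
$l_i$ as the normalised weighted sum

$$I_{\mathrm{thick}}(p) \;=\;
  \frac{\sum_i g(p, l_i, t)\, I_{\mathrm{thin}}(l_i)}
       {\sum_i g(p, l_i, t)}.$$

Two modelling commitments matter more than the exact kernel shape:

* **Positions are physical.** Slice centers live in the DICOM patient-based
  coordinate system, in mm. Target centers are generated as
  $p_k = s + k\,d$ over the thin-series extent $[s, e]$, where $d$ is the
  slice interval. They are never derived from slice indices, so the
  simulated grid matches what a scanner reconstructing at interval $d$
  would produce — including the case where the thick-series slice count is
  not the thin count divided by an integer factor.
* **Thickness and interval are independent.** $t > d$ yields overlapping
  slices, as clinical thick reconstructions often do; $t < d$ yields gaps.
  The kernel uses $t$; the grid uses $d$.

The three baselines (`simulate_direct_downsample()`,
`simulate_simple_average()`, `simulate_gaussian_average()`) intentionally
reproduce the index-based behaviour of the methods they stand for,
*including* their placement errors: direct downsampling keeps every
$n$-th slice at that slice's position; simple averaging places its output
at the group-mean position (for even group size there is no middle slice,
so the mean is used); Gaussian averaging smooths along the slice axis and
then decimates. "Fixing" their placement would remove exactly the
discrepancy the package exists to measure.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `interval` ($d$) | mm | — | distance between consecutive thick-slice centers |
| `thickness` ($t$) | mm | — | kernel half-width; axial extent of tissue mixing |
| `start`, `end` ($s$, $e$) | mm | thin-series extremes | extent walked by the location generator; overridable |
| `factor` | slices | — | decimation/group size for the baselines |
| `sigma` | slices | `factor / 2` | Gaussian-baseline standard deviation (its source describes no value; half the factor makes the kernel span roughly one output interval) |
| metric `window` | HU | $[-1024, 3071]$ | clip-and-rescale window before PSNR/SSIM; the full 12-bit CT range, recorded in every report |
| `tol` | mm | 0.5 | position-matching tolerance when pairing simulated with reference slices |

PSNR uses $\mathrm{MAX}_I = 1$ on the windowed unit scale, so reported
RMSE values are fractions of the 4095-HU window. SSIM uses the reference
parameterisation — $11 \times 11$ Gaussian window, $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$ — averaged over fully overlapping window
placements.

## Numerical choices

* Target locations are computed in closed form $s + k\,d$, not by repeated
  addition, so no floating-point drift accumulates along long series; the
  repeated-addition loop survives only as a test oracle. The loop bound is
  inclusive with tolerance $10^{-6}$ mm so that $e$ is kept whenever
  $(e-s)/d$ is integral despite rounding. When $(e-s)$ is not divisible by
  $d$, no extra slice is appended at $e$: the generator stops at the last
  on-grid point, which is what a scanner reconstructing on a fixed-pitch
  grid does.
* Weights are computed and accumulated in double precision, slice-major,
  and normalised once per output slice after accumulation. Weights are
  nonnegative and normalised, so every output voxel is a convex combination
  of thin voxels — the implementation cannot overshoot.
* A target location with zero total weight (a thin-series gap wider than
  $t$) is a hard error naming the location, never a silent skip: dropping
  it would silently corrupt the output grid.
* Slice matching (`match_positions()`) is greedy on $|\Delta z|$, each
  index used at most once; ties are resolved by candidate order, which is
  immaterial at the sub-tolerance distances involved.
* The Gaussian baseline truncates its kernel at $4\sigma$ and renormalises;
  near the volume ends the kernel is renormalised over its in-bounds
  support, so constants are preserved everywhere.
* Degenerate inputs: single-slice ranges ($s = e$) are valid and yield one
  slice; constant image pairs get SSIM 1 through the stabilising constants;
  identical pairs are reported with an infinite-PSNR flag and excluded from
  finite-PSNR aggregates (their count is reported alongside).

## The phantom as validation instrument

Real paired thin/thick acquisitions are rare — that scarcity is the
package's raison d'être — so validation uses analytic scenes: a background
(optionally affine in z), ellipsoid primitives, and axis-aligned z-slabs.
Slabs and the affine ramp are included because an ellipsoid cannot
represent a sharp z-step or a pure gradient, and those are exactly the
axial structures that expose placement and profile errors.

Two deliberately different forward models are used:

* `render_thin()` integrates the scene over a **boxcar** slab of width $t$
  (11-point quadrature by default) — a plausible model for a thin
  acquisition.
* `render_truth_thick()` integrates over the **triangular** profile of
  half-width $t$ by dense quadrature (101 points by default, an order of
  magnitude denser than what it judges).

Because the thin renderer does not share the triangular profile, the
simulator is tested on approximating a profile it was not handed — the
discrete weighted sum must *converge* to the continuous integral as the
thin spacing shrinks, and it does (RMSE falls monotonically over spacings
1, 0.5, 0.25 mm on the smooth preset).

Noise is seeded Gaussian HU noise with
$\sigma_{\mathrm{eff}} = \sigma_{\mathrm{HU}}\sqrt{t_{\mathrm{ref}}/t}$,
$t_{\mathrm{ref}} = 1$ mm, modelling the photon-statistics penalty of
thinner slices. The benchmark default is $\sigma_{\mathrm{HU}} = 10$ HU at
1 mm — a typical low-dose thin-slice noise magnitude — chosen once when the
benchmark was designed.

What the phantoms do **not** emulate: reconstruction-kernel texture and
noise correlation, beam hardening, motion, anatomy-scale structure, and
scanner-specific slice sensitivity profiles (real profiles are
kernel- and collimation-dependent; the triangle is an idealisation). A
passing benchmark therefore shows the geometry and weighting are right, not
that simulated volumes are indistinguishable from clinical thick slices.

## The benchmark

`compare_methods_phantom()` renders the smooth preset at 1 mm, adds seeded
noise (10 replicates), simulates $t = 3$ mm / $d = 2$ mm thick slices with
all four methods and scores each against the dense-quadrature truth on a
$32 \times 32 \times 21$ grid — sizes chosen to keep a full run in tens of
seconds while leaving hundreds of slice pairs per method. The expected
outcome is an ordering, not a number: the weighted-sum method outranks
every baseline in mean PSNR. On smooth scenes the Gaussian baseline is the
closest competitor (its profile, though misplaced, is peaked); on
edge-dominated scenes its blur costs more.

```{r, eval = FALSE}
res <- compare_methods_phantom(seed = 1, n_phantoms = 10)
res[, c("method", "psnr_mean", "rmse_mean", "ssim_mean")]
```

`scripts/acceptance.R` runs exactly this plus the convergence study and
writes the results as JSON.

## Design notes

* Volumes are a plain S3 container (`axial_volume`) holding the voxel
  array with its physical metadata; everything naturally tabular — slice
  locations, position matches, per-slice metrics, benchmark summaries —
  is a tibble, and fitted-result objects support `tidy()`, `glance()` and
  `autoplot()`.
* DICOM support is a purpose-built explicit-VR little-endian reader/writer
  for single-frame CT covering the geometry attributes the method needs
  (positions, orientation, thickness, spacing, rescale); it is
  cross-checked against pydicom in the test suite. Oblique or
  gantry-tilted series are rejected rather than resampled: the method's
  correctness argument lives in axial patient coordinates.
* NIfTI affines are taken literally (no RAS/LPS sign juggling): the z
  column provides spacing and origin, negative steps are flipped to
  ascending, and a JSON sidecar carries the slice thickness NIfTI cannot
  store. Round-tripping through `save_volume()`/`load_volume()` is exact
  to float32 quantisation.
* Real thick-series z-origins need not coincide with thin-series starts;
  `slice_geometry()` therefore accepts explicit `start`/`end` overrides,
  and evaluation is always position-matched with an explicit tolerance
  rather than index-aligned.

## Limitations

The triangular profile is an idealisation of reconstruction z-weighting;
scanner profiles vary with kernel and collimation. The baselines are
faithful to their index-based sources, so their scores should be read as
"what the conventional shortcut costs", not as the best those families
could do. FID-style learned-feature metrics are out of scope (they require
trained network weights); the metric report is limited to
PSNR/MSE/RMSE/SSIM.
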