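# ctsim

Physically grounded simulation of thick-slice CT volumes from thin-slice
acquisitions, for building realistic LR–HR training pairs for CT
super-resolution.

## The problem

Deep-learning super-resolution models that map thick-slice CT (e.g. 3–5 mm)
to thin-slice CT (≈1 mm) need paired training data, which routine scanning
almost never produces. The usual workaround — simulating thick slices from
thin ones by dropping every n-th slice, averaging groups of n slices, or
Gaussian-smoothing and decimating — operates on *slice indices* and ignores
the physical geometry of the scan. Two things go wrong:

1. **Slice misplacement.** Real thick series live on their own grid of
   physical z-positions (slice interval *d*), which generally does not
   coincide with any subset of thin-slice indices. Index-based methods put
   simulated slice centers in the wrong place in patient coordinates.
2. **Wrong axial profile.** A reconstructed slice of thickness *t* mixes
   tissue over an axial neighbourhood with a slice sensitivity profile that
   is peaked at the slice center — not a boxcar over *n* slices and not a
   point sample.

`ctsim` addresses both. Target slice centers are placed in the DICOM
patient-based coordinate system by walking the thin-series extent
`[s, e]` in steps of the interval *d*:

    L_thick = { s + k·d : k = 0, 1, 2, …,  s + k·d ≤ e }

and each thick slice at position *p* is a normalised weighted sum of all thin
slices at positions *l*, with the triangular slice-sensitivity weight
(inspired by the z-weighting of weighted filtered back projection):

    g(p, l, t) = max(0, 1 − |p − l| / t)
    I_thick(p) = Σ_l g(p, l, t) · I_thin(l)  /  Σ_l g(p, l, t)

Thickness *t* and interval *d* are independent parameters, so overlapping
thick slices (t > d, common clinically) come out naturally.

The three conventional baselines (direct downsampling, simple averaging,
Gaussian averaging) are included *with* their index-based placement
behaviour, because the point of having them is to quantify the error that
behaviour causes. Fidelity is scored per matched slice pair with
PSNR / MSE / RMSE / SSIM after windowing intensities to [0, 1] over a
configurable HU window (default [−1024, 3071], `max_i` = 1).

An analytic phantom module (ellipsoid/slab scenes evaluable at any
continuous point) provides thin-slice renderings plus dense-quadrature
ground-truth thick slices, so the simulator can be validated without any
clinical data.

## Worked example

```r
library(ctsim)

# paired fixture: 1 mm thin slices (seeded 10 HU noise) + ground truth
# thick slices (t = 3 mm, d = 2 mm) of a smooth ellipsoid phantom
ph <- cmd_phantom(tempfile(), preset = "blobs", seed = 7,
                  thin_interval = 1, thin_thickness = 1,
                  thick_interval = 2, thick_thickness = 3,
                  z_start = 0, z_end = 40)

thick <- simulate_proposed(ph$thin, slice_geometry(0, 40, 2, 3))
thick$positions[1:5]
#> [1] 0 2 4 6 8

rep <- evaluate_volumes(thick, ph$truth, tol = 0.5)
glance(rep)[, c("psnr_mean", "psnr_sd", "rmse_mean", "ssim_mean")]
#> # A tibble: 1 × 4
#>   psnr_mean psnr_sd rmse_mean ssim_mean
#>       <dbl>   <dbl>     <dbl>     <dbl>
#> 1      58.3   0.758   0.00122     0.998
```

The mean PSNR of ≈58 dB says the simulated thick slices differ from the
continuous-profile ground truth by about 0.12% of the 4095-HU window per
pixel (RMSE ≈ 0.0012 on the unit scale) — most of it residual acquisition
noise, since the triangular weights average ~5 noisy thin slices. Running
the same comparison with `simulate_simple_average()`,
`simulate_gaussian_average()` or `simulate_direct_downsample()` in place of
`simulate_proposed()` gives visibly lower PSNR (see the benchmark below);
`tidy(rep)` returns the per-slice table and `autoplot(rep)` plots the
metrics along z.

A shell entry point wrapping the same functions ships at
`inst/cli/ctsim.R` (`simulate`, `evaluate`, `phantom` subcommands; every run
writes a JSON manifest of its resolved parameters).

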