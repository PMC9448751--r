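# flow4d

Resolution-sensitivity analysis of 4D-Flow-MRI-derived hemodynamics.

4D-Flow MRI yields a time-resolved 3-component velocity field per voxel.
Everything computed from it — segmented vessel geometry, inlet boundary
conditions for CFD, plane velocities, wall shear stress (WSS) — depends on
the scan's spatial resolution, and clinical aortic protocols span a wide
range (roughly 1.5–4 mm isotropic). `flow4d` implements a complete,
ground-truth-controlled version of the four-resolution study design used to
quantify that dependence: virtual scans of the same flow at 4, 3, 2 and
1.5 mm, run through an identical analysis pipeline and compared against an
analytic reference.

The ground truth is Womersley pulsatile flow in a rigid straight tube,
driven by a harmonic decomposition of a cardiac-style flow waveform
$Q(t) = \mathrm{Re}\{\sum_k Q_k e^{ik\omega t}\}$:

$$
u(r,t) = \frac{2Q_0}{\pi R^2}\Bigl(1-\tfrac{r^2}{R^2}\Bigr)
 + \mathrm{Re}\sum_{k\ge 1}\frac{Q_k}{\pi R^2}\,
 \frac{1 - J_0(\beta_k r/R)/J_0(\beta_k)}
      {1 - 2J_1(\beta_k)/(\beta_k J_0(\beta_k))}\,e^{ik\omega t},
 \qquad \beta_k = i^{3/2} R\sqrt{k\omega/\nu} .
$$

The package provides:

* **flow model** — waveform construction and Fourier decomposition, the
  Womersley velocity profile and its closed-form wall shear stress, with
  complex-argument Bessel functions accurate to 1e-10;
* **virtual scanner** — partial-volume voxelization onto isotropic grids
  (4³ subsample rule, boundary voxels diluted by zero-velocity static
  tissue), frame-center temporal sampling, venc-scaled phase-contrast noise
  ($\sigma_v = \sqrt2\,\mathrm{venc}/\pi\,\mathrm{SNR}$), optional phase
  wrapping, NIfTI I/O;
* **geometry** — magnitude-threshold lumen segmentation, slice areas,
  equivalent diameters;
* **inlet boundary conditions** — per-frame velocity extraction, degree-4
  bivariate polynomial surface fits with temporal interpolation and no-slip
  clamping, voxel-sum volumetric flow rate;
* **hemodynamics** — systolic (peak ±1 frame) and diastolic phase windows,
  plane max/mean velocity magnitude, eight-sector WSS from wall-inward ray
  fits;
* **resolution study** — symmetric percent difference, mean ± sample-SD
  summaries, the exact Wilcoxon signed-rank test, a seeded multi-offset
  sweep orchestrator, and bundled worked-example tables from a published
  four-resolution aortic comparison whose derived columns the statistics
  reproduce cell by cell.

## Worked example

```r
library(flow4d)

w  <- make_waveform()                       # cardiac-style Q(t), T = 0.9 s
d  <- decompose_waveform(w, n_harmonics = 8)
v  <- vessel_model()                        # R = 12.5 mm straight tube
fl <- fluid_properties()                    # blood: 1060 kg/m^3, 3.5 mPa s

womersley_number(v$radius, d$omega, fl$kinematic_viscosity)
#> [1] 18.17597
velocity_profile(d, v, fl, r = 0, t = 0.19)   # near-peak centerline, m/s
#> [1] 0.6282095
analytic_wss(d, v, fl, t = 0.19)              # wall shear stress, Pa
#> [1] 1.832176
```

The four-resolution sweep acquires the field at each voxel size, segments,
extracts inlet flow, windows the cycle, and measures plane velocities and
eight-sector WSS, comparing against the analytic reference at the same
frame times (three grid offsets here for speed; studies use ten):

```r
sw <- resolution_sweep(seed = 1, n_offsets = 3)
subset(as.data.frame(sw), quantity %in% c("peak_flow", "wss_systole"))
#>    resolution_mm    quantity measured reference percent_difference
#> 1            4.0   peak_flow 2.36e-04  2.42e-04              2.134
#> 8            4.0 wss_systole 1.68e-01  1.45e+00            158.501
#> 10           3.0   peak_flow 2.36e-04  2.42e-04              2.414
#> 17           3.0 wss_systole 2.16e-01  1.45e+00            148.196
#> 19           2.0   peak_flow 2.39e-04  2.42e-04              1.006
#> 26           2.0 wss_systole 3.20e-01  1.45e+00            127.658
#> 28           1.5   peak_flow 2.42e-04  2.43e-04              0.510
#> 35           1.5 wss_systole 4.09e-01  1.58e+00            117.860
```

Reading the table: the voxel-sum peak flow is below truth everywhere and
converges as voxels shrink (2.1% low at 4 mm, 0.5% at 1.5 mm), while the
voxel-side WSS collapses severalfold at every resolution — the near-wall
gradient lives in a boundary layer thinner than any of the voxel sizes —
recovering monotonically toward the analytic value with refinement.

The comparison statistics reproduce the bundled worked-example tables'
printed columns exactly:

```r
rp <- reproduce_reference_tables()
subset(rp$velocity, table == "inlet_velocity_systole")
#>                    table resolution_mm pct_diff_umax printed_pct_diff_umax
#> 5 inlet_velocity_systole           4.0        1.9040                1.9040
#> 6 inlet_velocity_systole           3.0        1.9310                1.9310
#> 7 inlet_velocity_systole           2.0        0.3001                0.3001
#> 8 inlet_velocity_systole           1.5        1.1439                1.1440
#>   pct_diff_umean printed_pct_diff_umean
#> 5         23.370                 23.370
#> 6         18.556                 18.560
#> 7         12.979                 12.980
#> 8          8.192                  8.192

wilcoxon_signed_rank(2:9, 1:8)
#> Wilcoxon signed-rank: W = 36, n = 8, p = 0.0078125 (exact)
```

See `vignettes/resolution-sensitivity.Rmd` for the model, the acquisition
physics, every tunable parameter, and the design's limitations.

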