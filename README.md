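# skinqa — image quality for stretchable scintillator X-ray detectors

`skinqa` evaluates the imaging performance of stretchable scintillator
X-ray converters ("imaging skins"): silicone–GOS:Tb sheets that emit
visible light under X-rays and are photographed by an external scientific
camera. Because such a detector moves, deforms and stretches inside the
camera frame, the package re-detects the detector region in every session
and restricts all statistics to it. It is written for detector physicists
and instrumentation researchers who need the standard image-quality chain
— flat-field correction, signal-transfer-property (STP) linearity,
slanted-edge spatial frequency response (e-SFR) — on a deformable detector,
plus the stretch-specific analyses (volume-conserved thickness, metric
trends versus elongation, histogram drift).

The core quantities:

* **Flat-field correction** over the detected region *R*:
  `I_corr = (Ī_raw − Ī_dark) / (Ī_flat − Ī_dark) · m`, with
  `m = mean_R(Ī_flat − Ī_dark)` and Ī the 10-frame average.
* **STP**: `MPV(A_k) = (1/N) Σ_{(i,j)∈R} p_ij` versus air kerma
  `A_k = d·t`; OLS fit, R², and the 2% maximum-deviation linearity rule.
* **e-SFR**: slanted-edge (2–7°) estimate of the frequency response in
  lp/mm — sub-pixel edge location, 4× oversampled ESF, derivative,
  Hamming window, DFT with derivative-sinc correction — summarised by
  SFR50 and SFR10 (first crossings of 0.5 and 0.1).
* **Stretching**: elongation `(L − L0)/L0 × 100`, thickness
  `t = t0·A0/A` under volume conservation from detected areas, trend fits
  versus elongation, and Bhattacharyya distance `−ln Σ√(p_i q_i)` between
  mean-removed pixel histograms.

A seeded synthetic frame simulator (`synthetic_scene()`,
`make_frame_stack()`, `make_stp_series()`, `make_slanted_edge_scene()`,
`make_stretch_series()`) reproduces the statistical structure of the rig
— linear dose response, Gaussian PSF, Poisson + Gaussian frame noise,
volume-conserved stretch geometry — so the whole chain runs and is tested
without hardware.

## Worked example

Simulate an 8-exposure STP series at 2 mGy/s on a 340×340 px scene
(detected region ≈ 10⁵ pixels, 10-frame averaging), then fit MPV versus
air kerma:

```r
library(skinqa)

cfg   <- detector_config()   # 0.051 mm pitch, 10 frames, 12-bit range
scene <- synthetic_scene(c(340, 340), rect_polygon(340, 340, 6.5))
series <- make_stp_series(scene, cfg,
                          exposure_times_ms = c(20, 50, 100, 150, 200, 300, 400, 500),
                          dose_rate = 2, seed = 101)
ana <- stp_analysis(series)
ana$fit
#> <stp_fit>
#>   MPV = 3499.99 * A_k + 0.00691154
#>   R^2 = 1.0000000; max relative deviation = 0.00331% -> linear
```

The fitted slope recovers the scene's generating response
(3500 DN/mGy), the intercept is at the dark level after dark subtraction
(≈ 0), and the series passes the linearity rule: no point deviates more
than 2% from the fit, and R² is 1 to seven decimals at the calibrated
noise level.

The slanted-edge chain against its analytic oracle — a Gaussian PSF of
σ = 0.2 mm has MTF `exp(−2π²σ²f²)`, hence a half-height frequency of
0.937 lp/mm:

```r
sc <- make_slanted_edge_scene(4.5, psf_sigma_mm = 0.2, config = cfg,
                              shape_px = c(340, 340), margin = 14)
st <- make_frame_stack(sc, cfg, air_kerma = 0.2, seed = 77)
m  <- average_frames(st) - sc$response_offset
curve <- esfr_analysis(edge_roi(m[41:300, 31:310], pitch_mm = cfg$pixel_pitch_mm))
curve
#> <sfr_curve> 150 frequencies up to Nyquist 9.804 lp/mm
#>   SFR50 = 0.937 lp/mm, SFR10 = 1.702 lp/mm
```

And a stretch series, 0–100% elongation in 20% steps with
volume-conserved thinning from 0.5 mm:

```r
base   <- synthetic_scene(c(340, 340), rect_polygon(340, 340, 86.5))
series <- make_stretch_series(base, seq(0, 100, 20), config = cfg, seed = 55)
dark   <- make_frame_stack(base, cfg, 0, seed = 56, label = "dark")
stretch_analysis(series, dark_stack = dark)$table
#>   elongation_pct      mpv area_ratio thickness_mm bhattacharyya
#> 1              0 1750.053   1.000000    0.5000000   0.000000000
#> 2             20 1662.512   1.103208    0.4532237   0.001971910
#> 3             40 1574.972   1.178691    0.4241995   0.002554568
#> 4             60 1487.511   1.274205    0.3924015   0.003252132
#> 5             80 1400.015   1.340978    0.3728621   0.004442069
#> 6            100 1312.536   1.421687    0.3516949   0.005983208
```

MPV declines linearly (the 70 kVp regime), the detected-area ratios track
the volume-conserving geometry (thickness 0.50 → 0.35 mm at 100%), and the
mean-removed histogram drift stays far below the 0.35 level that marks
approach to rupture.

The numbered scripts under `analysis/` run these studies end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # seeded TIFF stacks for all presets
Rscript analysis/02_preprocess.R  # ROI detection + flat-field correction
Rscript analysis/03_stp.R         # STP fit + variant slope table
Rscript analysis/04_esfr.R        # SFR curves and SFR50/SFR10
Rscript analysis/05_stretch.R     # stretch table, trends, border zones
```

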