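---
title: "Image-quality evaluation for stretchable scintillator X-ray detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-quality evaluation for stretchable scintillator X-ray detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinqa)
```

## The measurement problem

A stretchable X-ray converter — a silicone elastomer loaded with a
GOS:Tb phosphor, here called an *imaging skin* — turns incoming X-rays into
visible light that an external scientific camera photographs. Unlike a rigid
flat-panel detector, the skin moves, deforms and stretches inside the camera
frame, so none of the usual image-quality machinery can assume a fixed
detector geometry. `skinqa` implements the evaluation chain for such a
detector:

1. **Pre-processing** — frame averaging, automatic detection of the skin
   region on a dark-corrected flat image, and gain/offset correction
   restricted to that region:
   \[
   I_{\mathrm{corrected}}
     = \frac{\bar I_{\mathrm{raw}} - \bar I_{\mathrm{dark}}}
            {\bar I_{\mathrm{flat}} - \bar I_{\mathrm{dark}}}\, m,
   \qquad
   m = \overline{\bar I_{\mathrm{flat}} - \bar I_{\mathrm{dark}}},
   \]
   with the bar denoting the 10-frame average and the outer bar the mean
   over the detected region.
2. **Signal transfer property (STP)** — mean pixel value (MPV) over the
   region versus air kerma \(A_k = d \times t\) (mean dose rate times
   exposure time), fitted by ordinary least squares. The detector counts as
   linear when no point deviates more than 2% from the fit.
3. **Edge spatial frequency response (e-SFR)** — the slanted-edge estimate
   of the system frequency response (the analogue of the presampled MTF),
   summarised by SFR50 and SFR10 in lp/mm.
4. **Stretch analysis** — elongation bookkeeping
   \((L-L_0)/L_0 \times 100\), volume-conserved thickness estimation
   \(t = t_0 A_0 / A\), metric trends versus elongation, and Bhattacharyya
   distances between mean-removed pixel histograms.

Because no public data exist for this class of detector, the package ships a
seeded simulator that reproduces the *statistical* structure the analyses
assume; every stage is exercised against it.

## The synthetic detector model

`synthetic_scene()` + `make_frame_stack()` render what the camera would see:
a bright polygonal skin region on a dark background with

* a linear dose response: expected in-skin value
  `response_offset + response_slope * air_kerma`;
* an optional opaque straight edge at a configurable slant (the simulated
  lead-bar phantom), rendered with one-pixel aperture anti-aliasing so that
  an unblurred edge carries the square-pixel sinc envelope;
* a Gaussian optical PSF specified in millimetres and converted through the
  pixel pitch, applied to the noiseless scene (`exp(-2*pi^2*sigma^2*f^2)` is
  then the analytic frequency-response oracle, `gaussian_mtf_reference()`);
* per-frame noise drawn *after* the blur: Poisson shot noise
  (`poisson_scale` photons per pixel unit) plus Gaussian read noise.

Default parameters mirror the reference rig: 0.051 mm effective pixel pitch,
10 frames averaged per acquisition, 100 ms exposure, and a 12-bit signal
range (`full_scale = 4095`) stored in 16-bit containers. The digitizer depth
is not part of the public record for the camera; 12 bit is typical for the
instrument class and makes the MPV uncertainty scale (≤ 1.72 DN) meaningful.
The default noise levels (read noise 2 DN per frame, 5 photons per DN) put
the repeat-MPV standard deviation far below that bound once ~10⁵ region
pixels and 10 frames are averaged — the calibration the linearity study
assumes. The simulated ADC does not quantize; at these noise levels
quantization would be invisible, and exact expected values make the
noiseless contracts testable to machine precision.

What the simulator does **not** model: X-ray spectra, scintillation yield,
optical scatter in the phosphor, camera gain and fixed-pattern
non-uniformity beyond what flat-fielding removes, geometric distortion, and
surface warping under stretch. Passing tests therefore demonstrate that the
*analysis chain* is correct and well-conditioned, not that a physical
detector meets any particular specification.

## Region detection

The skin region is detected on the dark-corrected flat acquired at the
highest dose of the session, where contrast is maximal: Otsu threshold,
3×3 morphological closing, largest connected component, hole filling, then
exclusion of pixels with `flat - dark <= eps` (default
`full_scale * 1e-4`) so the later division is safe. The method is
deterministic; when several components survive thresholding the largest is
kept and the event is logged. An optional erosion (`border_margin_px`)
excludes the border band where optical effects can dominate. Coordinates are
R-native: 1-based `(row, col)` matrix indexing, pixel-centre convention.

## The slanted-edge chain

The e-SFR implementation follows the canonical slanted-edge lineage:

1. per scan line, the edge position is the centroid of the absolute
   central-difference derivative, computed in a ±20 px window that *tracks*
   the edge (first around each row's own derivative peak, then, in a second
   pass, around the line fitted to the first-pass positions). The tracking
   window matters: with a fixed window, symmetric noise drags every
   centroid toward the window centre and biases the slant estimate low;
2. a straight line fitted to position versus row gives the slant angle; the
   protocol window is 2–7°, validated with a ±0.1° allowance for the
   estimate's own uncertainty; residual RMS above 1 px aborts ("edge not
   straight");
3. pixels are projected onto signed distance from the line and binned at
   `pitch / 4` (oversampling 4×, configurable); empty bins are filled by
   linear interpolation, and more than 20% empty bins aborts ("insufficient
   slant coverage" — an exactly axis-aligned edge has no phase diversity);
4. the line-spread function is the central-difference derivative of the
   binned ESF; a Hamming window centred on the (leftmost) LSF peak, full
   LSF width, suppresses tail noise;
5. the DFT magnitude is corrected for the derivative filter's sinc
   response, normalized to 1 at zero frequency, converted to lp/mm and
   truncated at the detector Nyquist `1/(2 * pitch)`;
6. SFR50/SFR10 are the first downward crossings of 0.5/0.1, scanning from
   zero frequency upward with linear interpolation (first-crossing search
   protects against noisy re-crossings); absent crossings are reported as
   "beyond Nyquist".

Two numerical choices deserve a note. The derivative-filter correction and
the Hamming window are both configurable because variants of the method
family differ here; the defaults are the documented mainstream choice. And
the edge ROI should be wide relative to the blur: the full-width Hamming
window slightly narrows a line-spread function that occupies a large
fraction of the ROI (about a 3% SFR50 bias when the ROI is only ~65 blur
sigmas wide, under 1% at ~160). The validation suite uses ~280-pixel-wide
ROIs for blurs up to sigma = 0.4 mm (≈ 8 px), where the full chain matches
the analytic Gaussian MTF within 0.02 absolute up to 80% of Nyquist and
recovers slant angles to ±0.1° at SNR ≥ 100.

## STP and trend fitting

`fit_stp()` is an unweighted OLS fit (the protocol reports none), with the
per-point relative deviation measured against the *fitted* value — the
standard detector-linearization convention. R² is computed directly from
the residual and total sums of squares and equals the squared Pearson
correlation (a cross-check in the test suite). Replicate STP slopes
aggregate into variant tables with the across-iteration standard deviation
as the error bar (configurable; the protocol wording does not pin down the
estimator). A metric with zero variance yields slope 0 and R² reported as 0
with a `degenerate_response` flag rather than `NaN`.

## Stretch analysis

Elongation uses the marked gauge length (`(L - L0)/L0 * 100`); compression
is rejected. Thickness is never assumed: it is estimated from detected
areas via volume conservation, `t = t0 / (A/A0)`, and the identity
`t * (A/A0) = t0` holds exactly. The simulator, however, must pick a lateral
contraction to *generate* stretched scenes; it defaults to the
incompressible uniaxial model (width factor `1/sqrt(lambda)`) with pure
shear (width fixed) as the built-in alternative and accepts any
`function(lambda)`. The measured endpoint of the reference experiment
(0.5 → 0.26 mm at 120%) implies an area ratio of ≈ 1.92, between the two
closed forms — which is precisely why the analysis side works from measured
masks only.

The simulated in-skin signal declines *linearly* with elongation (default
25% at 100%), matching the behaviour observed at 70 kVp, where MPV falls
linearly with elongation; a thickness-coupled alternative
(`signal_model = "thickness"`) scales the response with the thinning ratio
instead. The non-monotone MPV behaviour reported at lower tube voltages
(self-absorption and warping effects) is outside the simulator's scope and
flagged as such here.

Distribution drift is quantified by the Bhattacharyya distance
\(-\ln \sum_i \sqrt{p_i q_i}\) between mean-removed histograms (256 bins
over the joint range of the compared pair; bins and range are analysis
choices, recorded as defaults). Removing the mean first isolates shape
changes from the overall signal decline. The textbook definition returns
+∞ for disjoint supports; `stretch_analysis()` therefore evaluates the
coefficient over the joint support and reports the excluded mass
separately, keeping distances finite and interpretable on noisy data.
Border zones are concentric distance-transform percentile bands
(`zone_partition()`), zone 1 being the outermost; they partition the region
exactly, with ties in the discrete distance map resolved deterministically
by scan order.

## Orchestration and reproducibility

`run_config()` + `run_pipeline()` tie the stages into one seeded run:
stacks are written as multi-page 16-bit TIFFs with JSON sidecars, analyses
as CSV/JSON, and a manifest records every output with its MD5 checksum plus
a hash of the scientific configuration. The same configuration and seed
reproduce every output byte for byte; timings and validation warnings go to
the log, not the manifest. The numbered drivers under `analysis/` are thin
narrative wrappers over these functions.

## Problem sizes and limitations

The validation studies use 340×340 px frames with rectangular skins
(≥ 10⁵ region pixels for linearity studies, matching the uncertainty
calibration), 8-exposure series from 20 to 500 ms at 2 mGy/s, stretch series
0–100% in 20% steps, and 20–100 seeded repeats per study — sizes chosen so
the full suite documents the statistical claims while remaining quick to
re-run on a laptop. Rectangle vertices are placed on half-integer
coordinates so pixel-centre rasterization is area-exact; with arbitrary
real contours, expect ~1% discretization error in area ratios (the
tolerance the thickness checks carry).

Known limitations: the ROI detector assumes a single, high-contrast skin;
the e-SFR chain assumes one straight edge and degrades gracefully but
detectably outside the 2–7° window; the simulator's noise is spatially
white, so flat-field correction looks more effective than it would on a
camera with structured fixed-pattern noise; and physical effects specific
to stretched scintillators (warping, self-absorption) are represented only
as their *observed* signatures (linear MPV decline), not modelled.
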