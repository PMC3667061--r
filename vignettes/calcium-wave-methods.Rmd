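---
title: "Methods: calibrating and characterizing propagating calcium waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating and characterizing propagating calcium waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cawave)
```

## The measurement and its model

Fura-2 is a ratiometric calcium indicator: its emission excited at 340 nm
rises and at 380 nm falls as Ca²⁺ binds, so the 340:380 intensity ratio
indexes intracellular calcium independently of dye loading.  A mechanical
stimulus to one cell releases calcium that propagates outward through the
tissue; `cawave` assumes that propagation is **radially symmetric** about a
single source and that the local time course of the calcium excess above
the pre-stimulus (basal) level is a gated decaying pulse,

$$f(t) = H(t - t_0)\, A\, e^{-(t - t_0)/\tau}
\qquad\text{or}\qquad
f(t) = H(t - t_0)\, A\, \frac{\tau^2}{\tau^2 + (t - t_0)^2},$$

with amplitude $A$ (ratio units), activation time $t_0$ (s) and decay rate
$\tau$ (s); $H$ is the Heaviside step with $H(0) = 1$, i.e. the wave is
present at the activation instant.  The mean propagation velocity is the
inverse slope of any monotone "front feature" time against radial
distance.  We do not convert the ratio to absolute calcium concentration;
all amplitudes stay in ratio units.

## Calibration chain and its assumptions

1. **Registration.** The stimulus may move the sample, so frames are
   rigidly aligned to the first frame.  Frames taken through different
   filters have incompatible intensity mappings; both images are therefore
   reduced to one small-scale layer of the starlet (à trous, B3-spline)
   wavelet transform — structures of 1 px (default) or 2 px — max–min
   rescaled to [0, 1], and the whole-pixel shift is read off the peak of
   the Fourier phase-correlation surface.  Only integer translations are
   estimated (the misalignments seen in practice are a few pixels and the
   alignment is rigid); shifted frames are padded by edge replication.
2. **Ratio.** One ratio frame per consecutive (340, 380) pair, guarded as
   `340 / (380 + 1e-6)` so dark pixels stay finite.  The ratio frame
   inherits the pair's acquisition time; time zero is the first frame.
3. **Bleaching correction.** The two channels bleach with different
   e-folding times, which leaves a slow multiplicative drift on the ratio.
   The total flux (sum over pixels) of the **pre-stimulus** ratio frames is
   fitted with $a\,e^{-t/T} + c$ and the whole sequence is multiplied by
   $\mathrm{flux}(0)/\mathrm{flux}(t)$.  Post-stimulus frames are never
   fitted (the signal does not return to basal within the recording), only
   extrapolated over.  The correction is multiplicative because the drift
   it removes is a gain, not an offset.  A near-constant flux short-cuts to
   the identity correction; a non-converged fit falls back to a log-linear
   slope, flagged.
4. **Basal estimate.** Pre-stimulus ratio frames are averaged per pixel
   with one sigma-reject pass: survivors are the values *strictly inside*
   mean ± σ·(population SD across frames), with σ = 2 by default; constant
   series keep everything, and a pixel that rejects everything falls back
   to its unclipped mean.  The strict inequality matters at the exact
   boundary: a lone gross outlier among equal values deviates by exactly
   2 population SDs and must be discarded.
5. **Wave extraction.**
   `wave = median_filter(max(ratio − basal, 0))`: only released calcium is
   of interest, negative excursions are noise, and a small median filter
   (3×3 by default, never larger than 5×5) suppresses the ratio-amplified
   noise while preserving small structures.  Per-pixel statistics —
   maximum, time of maximum (earliest tie), mean, SD — are computed on the
   filtered stack, i.e. noise reduction precedes statistics.

## Global and local analysis

The **source** is found on the wave image at the stimulus frame: 3×3
grayscale opening, rescale to [0, 1], zero everything below 0.2, then an
iterative centre of mass in which each iteration halves the window per
dimension, re-centred on the previous estimate, until the next window
would drop below 20 px a side.  The homing-in makes the estimate follow
the biggest, brightest structure rather than secondary releases.  If
thresholding empties the image an error asks for manual coordinates.

**Ring reduction** groups pixels into one-pixel-wide half-open annuli
($r \le d < r+1$, Euclidean distance in px to the source) and averages
each ring per frame, optionally over masked pixels only (recommended: ring
means are then dominated by stimulated cells).  Rings partition the disc,
so count-weighted ring sums conserve the disc sum exactly — a standing
invariant in the tests.

**Velocities.** Per radial bin we take the time of the maximum ring value
(`max_intensity`) or of the maximum positive forward difference
(`max_gradient`; the temporal gradient is computed on ring averages, the
simplest estimator of the "maximum increase", and the difference between
frames $t$ and $t+1$ is assigned to time $t$ — a constant offset that
cannot bias the slope).  Feature time is regressed on radius with
iterative 2σ outlier rejection; the velocity is the inverse slope in px/s
and, times the pixel size (default 1.025 µm/px), in µm/s.  A non-positive
slope is flagged non-physical rather than inverted.  Each rejection pass
re-evaluates **all** points against the current line, so inliers dropped
while a gross outlier tilted the first fit are recovered once it is gone;
the rejection band has a scale-relative floor (`1e-8` of the data range)
so exactly collinear data cannot collapse the survivor set.  Far from the
source the per-ring maximum decays approximately linearly with radius;
extrapolating that robust line to zero (for radii beyond `r_min`, default
10 px) estimates the maximum propagation radius.  A numerically zero slope
leaves the crossing undefined.

**Model fits.** The gated decay model is fitted per radius (and, in the
local analysis, per masked pixel) by Levenberg–Marquardt
(`minpack.lm::nls.lm`, bounds $A \ge 0$, $t_0$ within the acquisition
span, $\tau > 0$).  Initialization: $t_0$ one sample after the maximum
forward difference (or at the series maximum when the series already
decays from its first sample — the gate has a jump there and a start on
the wrong side of it stalls the optimizer), $A$ at the series maximum,
$\tau$ at a quarter of the post-onset span; the local analysis can seed
$A$ and $t_0$ from the per-pixel statistics instead, which shortens the
optimization.  After the 3-parameter fit, $(A, \tau)$ are polished with
$t_0$ held fixed — that subproblem is smooth, and the polish tightens the
estimates past the kinked geometry near the gate.

One genuine identifiability limit is handled explicitly: for the
*exponential* model, noiseless post-activation samples determine only
$A\,e^{t_0/\tau}$, so every $t_0$ inside the sampling interval bracketing
the onset fits with zero residual.  When the optimum is degenerate in this
sense (relative residual below $10^{-6}$) the fit resolves $t_0$ to the
first strictly positive sample — where the model attains its peak — and
refits $(A, \tau)$.  Noisy series never trigger the tie-break.  The
consequence for users: activation times from sparsely sampled data carry
an intrinsic uncertainty of one frame period, which is also why the
single-filter mode's higher frame rate improves velocity estimates.
Non-converged per-radius fits are dropped from downstream regressions;
non-converged pixels keep the sentinel 0 in the local parameter maps
(rendering black) while their residual is still recorded.

**Masking.** The per-pixel maximum image is thresholded at
`median + 1·SD` — the median stands in for the background level because it
is robust to the bright wave region — and cleaned by closing then opening
with disc structuring elements (7 px default; order and sizes are
configurable because their interaction is data-dependent and the original
procedure relies on visual inspection).  An empty mask is a warning, not
an error, and the pipeline then proceeds unmasked.

**One-filter mode.** A pure 380 nm stream skips the second exposure and
filter-wheel rotation, so it samples 2–3× faster.  The same chain runs
without the ratio step and with the sign inverted
(`wave = max(basal − frame, 0)`), since 380 nm emission falls as calcium
binds.  Bleaching correction is applied by default for symmetry and can be
switched off.  Only the maximum-gradient velocity is offered: 380 nm
intensity maxima do not track the calcium maximum, and requesting the
max-intensity mode is a refused contract, not a silent fallback.

## The synthetic-experiment generator

`ground_truth()` + `generate_experiment()` synthesize interlaced sequences
in which the computed ratio is exact by construction: the 380 nm channel is
`base · texture · (1 − k·f/(basal+f))` and the 340 nm channel is the target
ratio times that, after which each channel gets its own bleaching factor
`exp(−t/decay_ch)`, per-frame integer shifts (wrap-around) and clipped
Gaussian noise.  Both exposures of a pair share the pair's nominal time, so
the only cross-channel ratio bias is the differential bleaching the
calibration is designed to remove.  Default study conditions, chosen to
mirror a typical epithelial recording: frame period 1 s (two-filter) or
1/2.8 s (single-filter), pixel size 1.025 µm/px, ≥ 10 basal frames, basal
ratio 1.0, 380 nm base level 0.35 of full scale, amplitude 0.5 ratio
units, τ = 20 s, wave footprint a disc covering well under half the frame.
The basal ratio level and channel signal-to-noise are free parameters, not
asserted facts.  A static multiplicative pixel-scale texture (±30%)
emulates the tissue structure that cross-channel registration keys on; it
cancels exactly in the ratio.  Optional knobs: linear radial taper of A
(to exercise the maximum-radius extrapolation) and of τ, and a radially
growing Gaussian jitter of activation times (`t0_dispersion`) emulating
the dispersion of cell ignition — under which the peak lags the front and
the gradient velocity must not fall below the intensity velocity.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: cell geometry and intercellular
delays, diffusion physics, spontaneous secondary releases, spatially
correlated noise, subpixel or non-rigid motion, and detector artifacts.

## Numerical conventions

* Pixel coordinates are 1-based `(row, col)`; radial distances are
  Euclidean in pixel units.  Same-channel frame $i$ is at time
  $(i-1)\cdot$`frame_period`; `stimulus_frame` is the first post-stimulus
  index, and the value `n + 1` denotes an all-basal sequence.
* Raw intensities are fractions of full scale (8-bit: /255, 16-bit:
  /65535); outputs are 32-bit float FITS, written by a deliberately
  minimal single-image-HDU reader/writer.
* Starlet boundaries are mirrored; the transform reconstructs the input
  exactly (detail layers + final smooth), which the tests assert at 1e-12.
* A constant image has an identically zero detail layer; degenerate
  max–min rescales return all-zero images rather than erroring, and
  featureless registration inputs return a zero shift with a warning flag.
* The median filter runs through `EBImage::medianFilter` on data rescaled
  to [0, 1], which quantizes at ~1.5e-5 of the local range — negligible
  against the 340/380 shot noise it suppresses; kernel 1 is the exact
  identity.
* Test and validation problem sizes: 96–128 px frames, 25–50 frame pairs,
  up to ~5,000 pixelwise fits — small enough to run the whole suite in a
  few minutes while leaving every estimator's accuracy measurable.

## Known limitations

Integer-pixel registration only; one wave per field of view (the source
finder returns the dominant structure); the decay models are deliberately
naive summaries, not diffusion physics; activation times are quantized by
the frame period as discussed; and mask quality on real tissue ultimately
still benefits from a visual check of the chosen threshold and
morphology — the defaults are sensible starting points, not guarantees.
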