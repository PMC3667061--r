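# cawave — calibration and velocimetry of propagating calcium waves

Intracellular Ca²⁺ released by a mechanical stimulus propagates through
ciliated epithelial tissue as a radially spreading wave, and its velocity,
amplitude and decay carry physiological information (for example, calcium
regulates ciliary beat frequency in the oviduct).  The standard readout is
ratiometric Fura-2 fluorescence imaging: frames are acquired alternating
340 nm and 380 nm excitation filters, and the 340:380 intensity ratio
indexes intracellular calcium.  Extracting wave parameters from such
sequences by hand — choosing sample regions, transcribing intensities,
thresholding the front — is slow and poorly reproducible.

`cawave` is an R package for biologists and image analysts that turns raw
interlaced frame sequences into calibrated wave stacks and wave
parameters, semi-automatically:

* **Calibration** — rigid frame registration by Fourier phase correlation
  on the pixel-scale starlet (à trous) wavelet layer (which makes frames
  from different filters comparable); 340:380 ratio computation; correction
  of the channel-specific fluorophore bleaching by fitting
  `flux(t) = a·exp(−t/T) + c` to the pre-stimulus total flux and
  flattening the whole sequence by `flux(0)/flux(t)`; sigma-clipped basal
  (pre-stimulus) estimation; wave extraction
  `w = median_filter(max(ratio − basal, 0))` with per-pixel maximum,
  time-of-maximum, mean and standard deviation maps.
* **Masking** — a binary region of interest from the statistics
  (threshold at one standard deviation over the background level, cleaned
  by morphological closing/opening with disc structuring elements).
* **Global analysis** — automatic source localization by an iterative,
  window-halving intensity centre of mass; reduction of the stack to a
  radial-distance × time map by averaging one-pixel-wide rings; mean
  propagation velocities from robust (outlier-rejecting) linear
  regressions of per-radius feature times against radius, where the
  feature is the maximum intensity or the maximum positive temporal
  gradient (the wave-front); extrapolated maximum propagation radius; and
  Heaviside-gated decay-model fits per radius,

      f(t) = H(t − t₀) · A · e^{−(t − t₀)/τ}            (exponential)
      f(t) = H(t − t₀) · A · τ² / (τ² + (t − t₀)²)      (quadratic)

  fitted by Levenberg–Marquardt; regressing the fitted activation times
  t₀ on radius gives a third velocity estimate.
* **Local analysis** — the same model fitted independently at every masked
  pixel, producing amplitude / activation-time / decay-rate maps.
* **One-filter mode** — velocity-only analysis from a pure 380 nm stream
  at a higher frame rate (the wave appears as an intensity *decrease*;
  only the maximum-gradient velocity is meaningful and the max-intensity
  mode is refused).
* **Synthetic experiments** — a ground-truth generator
  (`ground_truth()` / `generate_experiment()`) that synthesizes interlaced
  sequences with known source, velocity, per-pixel (A, t₀, τ), channel
  bleaching, misalignment, texture and noise, so every stage is testable
  by parameter recovery.

Sequences are read from 8/16-bit grayscale TIFF files; calibrated outputs
are written as 32-bit floating-point FITS plus plain-text manifests,
tables (CSV) and YAML configs/summaries.

## Worked example

```r
library(cawave)

truth <- ground_truth(shape = c(128, 128), source = c(64, 64), velocity = 5,
                      stimulus_frame = 12, amplitude = 0.5, tau = 20,
                      footprint_radius = 45)
ex  <- generate_experiment(truth, n_frames = 40, frame_period = 1, seed = 1)
run <- run_pipeline(run_config(verbose = FALSE), seq = ex$seq)
print(run)
#> <cawave_run>
#>   source: (64, 64)
#>   wave-front velocity (max gradient) : 5.099 px/s = 5.227 um/s
#>   peak velocity (max intensity)      : 5.099 px/s = 5.227 um/s
#>   activation-time velocity (model)   : 5.099 px/s = 5.227 um/s
#>   max propagation radius (extrapol.) : NA px
#>   mean decay rate                    : 20.01 s
```

The generated wave travels at 5 px/s; the three independent estimators
(time of per-ring maximum, time of maximum per-ring temporal gradient, and
regression of fitted activation times) all recover it within 2%, and the
mean fitted decay rate matches the generated τ = 20 s.  The maximum
propagation radius is `NA` here because the generated amplitude does not
taper with radius, so the linear amplitude-decay extrapolation is
correctly reported as undefined.  Velocities in µm/s use the configured
pixel size (default 1.025 µm/px).  On real data, start from
`read_sequence("dir/", frame_period = ..., stimulus_frame = ...)` instead
of the generator, or use the command-line wrapper
`inst/scripts/cawave.R` (`simulate`, `calibrate`, `mask`, `analyze`,
`local`, `onefilter`, `run`).

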