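# Synthetic two-filter / single-filter experiment generator with known
# ground truth, used to validate every pipeline stage by parameter recovery.

#' Ground truth for a synthetic calcium-wave experiment
#'
#' Describes a radially symmetric wave: activation at pixel `p` occurs
#' `distance(p, source) / velocity` seconds after the stimulus, after which
#' the ratio excess follows the Heaviside-gated decay model (see
#' [evaluate_model()]) with per-pixel amplitude and decay rate.  The wave
#' footprint is a disc around the source; outside it the amplitude is zero.
#' Amplitude and decay rate may optionally taper linearly with radius to
#' zero amplitude / half the central decay rate at the footprint edge.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param source wave origin `c(row, col)` (1-based pixel coordinates).
#' @param velocity propagation velocity in px/s (> 0).
#' @param stimulus_frame 1-based index of the first post-stimulus
#'   same-channel frame; at least 10 pre-stimulus frames are required for a
#'   usable basal estimate.
#' @param amplitude central wave amplitude, in ratio units.
#' @param tau central decay rate, seconds.
#' @param footprint_radius radius of the wave footprint in px.
#' @param basal_ratio pre-stimulus 340:380 ratio level.
#' @param decay_340,decay_380 e-folding times (s) of the fluorescence
#'   marker decay in each channel; `Inf` disables decay.
#' @param noise_sigma additive Gaussian noise sigma, as a fraction of full
#'   scale, applied per channel.
#' @param shift_per_frame optional integer matrix (one `(dy, dx)` row per
#'   raw frame) of frame misalignments.
#' @param amplitude_profile,tau_profile `"constant"` (default) or
#'   `"linear"` radial taper.
#' @param texture_amplitude amplitude of a static multiplicative pixel-scale
#'   texture field (uniform in `1 +/- texture_amplitude`) applied to both
#'   raw channels.  It emulates the spatial structure of real tissue that
#'   cross-channel registration keys on, and cancels exactly in the
#'   340:380 ratio.  Set to 0 for featureless frames.
#' @param t0_dispersion per-pixel activation-time jitter: Gaussian with
#'   standard deviation `t0_dispersion * distance / velocity` seconds is
#'   added to the nominal activation time (truncated at 0), emulating the
#'   growing spread of cell ignition times at larger radii.  Default 0
#'   (ideal radial front).
#' @param seed seed for the dispersion jitter (only used when
#'   `t0_dispersion > 0`).
#' @return an object of class `ground_truth` with the per-pixel maps
#'   `amplitude_map`, `tau_map`, `t0_map` (activation time in seconds after
#'   the stimulus), the logical `footprint`, and the scalar parameters.
#' @export
ground_truth <- function(shape, source, velocity, stimulus_frame,
                         amplitude = 0.5, tau = 20, footprint_radius = NULL,
                         basal_ratio = 1, decay_340 = Inf, decay_380 = Inf,
                         noise_sigma = 0, shift_per_frame = NULL,
                         amplitude_profile = c("constant", "linear"),
                         tau_profile = c("constant", "linear"),
                         texture_amplitude = 0.3, t0_dispersion = 0,
                         seed = NULL) {
  amplitude_profile <- match.arg(amplitude_profile)
  tau_profile <- match.arg(tau_profile)
  stopifnot(length(shape) == 2L, length(source) == 2L)
  if (!is.numeric(velocity) || velocity <= 0) stopf("velocity must be > 0 px/s")
  if (!is.numeric(tau) || tau <= 0) stopf("tau must be > 0 s")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (any(source < 1) || any(source > shape)) stopf("source must lie inside the frame")
  if (!is_count(stimulus_frame) || stimulus_frame < 11L)
    stopf("stimulus_frame must leave at least 10 pre-stimulus frames")
  footprint_radius <- footprint_radius %||% (min(shape) / 2 - 2)
  dist <- distance_map(shape[1L], shape[2L], source)
  inside <- dist <= footprint_radius
  taper <- function(profile, centre, edge_frac) {
    m <- matrix(0, shape[1L], shape[2L])
    m[inside] <- if (profile == "constant") centre else
      centre * (1 - (1 - edge_frac) * dist[inside] / footprint_radius)
    m
  }
  amplitude_map <- taper(amplitude_profile, amplitude, 0)
  tau_map <- taper(tau_profile, tau, 0.5)
  tau_map[!inside] <- tau                 # tau > 0 everywhere; A = 0 gates the wave
  t0_map <- dist / velocity
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed %||% 1L)
  texture <- if (texture_amplitude > 0) {
    matrix(runif(prod(shape), 1 - texture_amplitude, 1 + texture_amplitude),
           shape[1L], shape[2L])
  } else {
    matrix(1, shape[1L], shape[2L])
  }
  if (t0_dispersion > 0) {
    jitter <- matrix(rnorm(length(t0_map), sd = 1), shape[1L], shape[2L]) *
      t0_dispersion * t0_map
    t0_map <- pmax(t0_map + jitter, 0)
  }
  t0_map[!inside] <- Inf
  if (!is.null(shift_per_frame)) {
    shift_per_frame <- as.matrix(shift_per_frame)
    stopifnot(ncol(shift_per_frame) == 2L)
  }
  structure(list(shape = as.integer(shape), source = source,
                 velocity = velocity, stimulus_frame = as.integer(stimulus_frame),
                 amplitude_map = amplitude_map, tau_map = tau_map,
                 t0_map = t0_map, footprint = inside, texture = texture,
                 footprint_radius = footprint_radius, basal_ratio = basal_ratio,
                 decay_340 = decay_340, decay_380 = decay_380,
                 noise_sigma = noise_sigma, shift_per_frame = shift_per_frame),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d px, source (%g, %g), v = %g px/s\n",
              x$shape[1L], x$shape[2L], x$source[1L], x$source[2L], x$velocity))
  cat(sprintf("  footprint radius %g px, A = %g, tau = %g s, basal ratio %g\n",
              x$footprint_radius, max(x$amplitude_map), max(x$tau_map), x$basal_ratio))
  invisible(x)
}

# ratio-excess map at time `trel` seconds after the stimulus
truth_excess <- function(truth, trel, model_kind) {
  f <- matrix(0, truth$shape[1L], truth$shape[2L])
  on <- truth$footprint & (trel >= truth$t0_map)
  if (any(on)) {
    dt <- trel - truth$t0_map[on]
    A <- truth$amplitude_map[on]
    tau <- truth$tau_map[on]
    f[on] <- if (model_kind == "exponential") A * exp(-dt / tau)
             else A * tau^2 / (tau^2 + dt^2)
  }
  f
}

#' Generate a synthetic interlaced two-filter experiment
#'
#' Synthesizes an interlaced 340/380 nm sequence whose computed 340:380
#' ratio equals `basal_ratio` before the stimulus and
#' `basal_ratio + f(t - t_stim)` afterwards, with `f` the Heaviside-gated
#' decay model evaluated from the per-pixel ground-truth parameters.  The
#' 380 nm channel is synthesized as
#' `base_intensity * (1 - dip_fraction * f / (basal + f))` -- its emission
#' falls as calcium binds -- and the 340 nm channel as ratio times that, so
#' the ratio is exact by construction.  Each channel is then multiplied by
#' its own marker-decay factor `exp(-t / decay_ch)`, frames are translated
#' by the per-frame shifts (wrap-around), and clipped Gaussian noise is
#' added per channel.
#'
#' Both exposures of a pair share the pair's nominal acquisition time, so
#' the only cross-channel ratio bias is the differential marker decay that
#' the calibration stage is designed to remove.
#'
#' @param truth a [ground_truth()].
#' @param n_frames number of frame *pairs* (same-channel frames).
#' @param frame_period seconds between consecutive same-channel frames.
#' @param model_kind `"exponential"` or `"quadratic"` decay model.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param base_intensity pre-stimulus 380 nm level (fraction of full scale).
#' @param dip_fraction maximal fractional 380 nm dip at full wave amplitude.
#' @param pixel_size um/px recorded in the sequence metadata.
#' @return a list with elements `seq` (a [frame_sequence()], 2 * `n_frames`
#'   interlaced frames) and `truth`.
#' @export
generate_experiment <- function(truth, n_frames, frame_period,
                                model_kind = c("exponential", "quadratic"),
                                seed = 1L, base_intensity = 0.35,
                                dip_fraction = 0.5, pixel_size = 1.025) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.numeric(frame_period) || frame_period <= 0)
    stopf("frame_period must be > 0 seconds")
  if (!is_count(n_frames) || n_frames <= truth$stimulus_frame)
    stopf("n_frames must exceed stimulus_frame")
  if (!is.null(truth$shift_per_frame) && nrow(truth$shift_per_frame) < 2L * n_frames)
    stopf("shift_per_frame must have one row per raw frame (2 * n_frames)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  t_stim <- (truth$stimulus_frame - 1L) * frame_period
  d <- truth$shape
  frames <- array(0, dim = c(d[1L], d[2L], 2L * n_frames))
  channels <- rep_len(c("340", "380"), 2L * n_frames)
  for (i in seq_len(n_frames)) {
    t <- (i - 1L) * frame_period
    f <- truth_excess(truth, t - t_stim, model_kind)
    shape380 <- base_intensity * truth$texture *
      (1 - dip_fraction * f / (truth$basal_ratio + f))
    i380 <- shape380 * exp(-t / truth$decay_380)
    i340 <- (truth$basal_ratio + f) * shape380 * exp(-t / truth$decay_340)
    for (ch in 1:2) {
      raw_idx <- 2L * (i - 1L) + ch
      m <- if (ch == 1L) i340 else i380
      if (!is.null(truth$shift_per_frame))
        m <- roll_matrix(m, truth$shift_per_frame[raw_idx, ])
      if (truth$noise_sigma > 0)
        m <- m + matrix(rnorm(length(m), sd = truth$noise_sigma), d[1L], d[2L])
      frames[, , raw_idx] <- pmin(pmax(m, 0), 1)
    }
  }
  seq <- frame_sequence(frames, channels, frame_period = frame_period,
                        stimulus_frame = truth$stimulus_frame,
                        pixel_size = pixel_size)
  list(seq = seq, truth = truth)
}

#' Generate a synthetic single-filter (380 nm) experiment
#'
#' Produces only the 380 nm stream of [generate_experiment()], typically at
#' the higher sampling rate the one-filter mode permits (skipping the second
#' exposure and the filter-wheel rotation).  In this stream the passing wave
#' appears as an intensity *decrease* below the basal level.
#'
#' @inheritParams generate_experiment
#' @param frame_period seconds between consecutive 380 nm frames (the
#'   single-filter mode typically runs ~2-3x faster than the two-filter
#'   mode).
#' @return a [frame_sequence()] of `n_frames` frames labeled `"380"`.
#' @export
generate_single_filter <- function(truth, n_frames, frame_period,
                                   model_kind = c("exponential", "quadratic"),
                                   seed = 1L, base_intensity = 0.35,
                                   dip_fraction = 0.5, pixel_size = 1.025) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.numeric(frame_period) || frame_period <= 0)
    stopf("frame_period must be > 0 seconds")
  if (!is_count(n_frames) || n_frames <= truth$stimulus_frame)
    stopf("n_frames must exceed stimulus_frame")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  t_stim <- (truth$stimulus_frame - 1L) * frame_period
  d <- truth$shape
  frames <- array(0, dim = c(d[1L], d[2L], n_frames))
  for (i in seq_len(n_frames)) {
    t <- (i - 1L) * frame_period
    f <- truth_excess(truth, t - t_stim, model_kind)
    m <- base_intensity * truth$texture *
      (1 - dip_fraction * f / (truth$basal_ratio + f)) *
      exp(-t / truth$decay_380)
    if (!is.null(truth$shift_per_frame))
      m <- roll_matrix(m, truth$shift_per_frame[min(i, nrow(truth$shift_per_frame)), ])
    if (truth$noise_sigma > 0)
      m <- m + matrix(rnorm(length(m), sd = truth$noise_sigma), d[1L], d[2L])
    frames[, , i] <- pmin(pmax(m, 0), 1)
  }
  frame_sequence(frames, "380", frame_period = frame_period,
                 stimulus_frame = truth$stimulus_frame, pixel_size = pixel_size)
}

#' Write a frame sequence as numbered grayscale TIFF files
#'
#' One 8- or 16-bit file per frame; the filename pattern encodes acquisition
#' index and channel (`frame_0001_340.tif`), which [read_sequence()] parses
#' back.
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if needed).
#' @param bits 8 or 16 bits per sample.
#' @return the vector of written file paths, invisibly.
#' @export
write_sequence <- function(seq, dir, bits = 8L) {
  stopifnot(inherits(seq, "frame_sequence"), bits %in% c(8L, 16L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(seq$frames)[3L]
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(dir, sprintf("frame_%04d_%s.tif", i, seq$channels[i]))
    tiff::writeTIFF(pmin(pmax(seq$frames[, , i], 0), 1), files[i],
                    bits.per.sample = bits)
  }
  invisible(files)
}

#' Write ground truth as a plain-text sidecar plus FITS parameter maps
#'
#' Scalar parameters go to `truth.yaml`; the per-pixel amplitude, decay-rate
#' and activation-time maps are written as 32-bit FITS via
#' [write_outputs()].
#'
#' @param truth a [ground_truth()].
#' @param dir output directory.
#' @return invisibly, the sidecar path.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- truth[c("shape", "source", "velocity", "stimulus_frame",
                     "footprint_radius", "basal_ratio", "decay_340",
                     "decay_380", "noise_sigma")]
  side <- file.path(dir, "truth.yaml")
  yaml::write_yaml(lapply(scalars, function(v) if (is.numeric(v)) as.numeric(v) else v),
                   side)
  t0 <- truth$t0_map
  t0[!is.finite(t0)] <- -1  # sentinel: never activated
  write_outputs(list(truth_amplitude = truth$amplitude_map,
                     truth_tau = truth$tau_map,
                     truth_t0 = t0,
                     truth_footprint = truth$footprint * 1), dir)
  invisible(side)
}
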