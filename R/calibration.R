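# Calibration: ratio computation, marker-decay correction, basal
# estimation, and wave extraction with per-pixel statistics.

#' Compute the 340:380 ratio sequence
#'
#' Forms one ratio frame per consecutive (340, 380) pair; the ratio indexes
#' intracellular calcium.  Division is guarded by a small epsilon so dark
#' 380 nm pixels produce large but finite values.
#'
#' @param seq a registered two-filter [frame_sequence()].
#' @param eps guard added to the 380 nm denominator (fraction of full
#'   scale).
#' @return a ratio-labeled [frame_sequence()] with one frame per pair.
#' @export
compute_ratio <- function(seq, eps = 1e-6) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- dim(seq$frames)[3L]
  if (n %% 2L == 1L) {
    warnf("odd trailing frame dropped before ratio computation")
    n <- n - 1L
  }
  idx340 <- seq(1L, n, by = 2L)
  if (!all(seq$channels[idx340] == "340") || !all(seq$channels[idx340 + 1L] == "380"))
    stopf("compute_ratio needs strictly alternating 340/380 frames")
  if (min(seq$frames[, , seq_len(n)]) < 0) stopf("negative intensities in input")
  ratio <- array(0, dim = c(dim(seq$frames)[1:2], length(idx340)))
  for (k in seq_along(idx340))
    ratio[, , k] <- seq$frames[, , idx340[k]] / (seq$frames[, , idx340[k] + 1L] + eps)
  out <- frame_sequence(ratio, "ratio", frame_period = seq$frame_period,
                        stimulus_frame = seq$stimulus_frame,
                        pixel_size = seq$pixel_size)
  out$shifts <- seq$shifts
  out
}

#' Fit the fluorescence-marker decay from pre-stimulus flux
#'
#' The Fura-2 marker bleaches with a different e-folding time in each
#' channel, leaving a slow multiplicative drift on the computed ratio.  The
#' drift is estimated from the total flux (sum over all pixels) of the
#' ratio frames captured *before* the stimulus, by least-squares fitting
#' `flux(t) = amplitude * exp(-t / efold_time) + offset`.  Post-stimulus
#' frames are never fitted; the model is extrapolated over them by
#' [correct_marker_decay()].
#'
#' @param ratio_seq a ratio-labeled [frame_sequence()].
#' @param stimulus_frame 1-based index of the first post-stimulus ratio
#'   frame; defaults to the sequence metadata.
#' @return an object of class `decay_fit` with fields `amplitude`,
#'   `efold_time` (s), `offset`, `fitted_range` (frame indices used) and
#'   `converged`.  A near-constant flux yields the no-decay fit
#'   (`amplitude = 0`, infinite e-folding time).
#' @export
fit_marker_decay <- function(ratio_seq, stimulus_frame = NULL) {
  stopifnot(inherits(ratio_seq, "frame_sequence"))
  stimulus_frame <- stimulus_frame %||% ratio_seq$stimulus_frame
  n_pre <- stimulus_frame - 1L
  if (n_pre < 4L) stopf("need at least 4 pre-stimulus ratio frames, have %d", n_pre)
  flux <- apply(ratio_seq$frames[, , seq_len(n_pre), drop = FALSE], 3L, sum)
  t <- (seq_len(n_pre) - 1L) * ratio_seq$frame_period
  new_fit <- function(amplitude, efold_time, offset, converged, fallback = FALSE)
    structure(list(amplitude = amplitude, efold_time = efold_time,
                   offset = offset, fitted_range = seq_len(n_pre),
                   converged = converged, fallback = fallback),
              class = "decay_fit")
  rng <- diff(range(flux))
  if (rng <= 1e-9 * max(abs(flux), 1)) {          # no-decay limit
    return(new_fit(0, Inf, mean(flux), TRUE))
  }
  start <- c(amplitude = rng, efold_time = max(diff(range(t)), 1), offset = min(flux))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) flux - (p[1L] * exp(-t / p[2L]) + p[3L]),
      lower = c(-Inf, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$info %in% 1:4) {
    p <- fit$par
    return(new_fit(p[[1L]], p[[2L]], p[[3L]], TRUE))
  }
  # fall back to a log-linear fit with zero offset, flagged
  pos <- flux > 0
  if (sum(pos) < 2L) stopf("marker-decay fit failed: non-positive fluxes")
  ll <- lm(log(flux[pos]) ~ t[pos])
  efold <- -1 / coef(ll)[[2L]]
  if (!is.finite(efold) || efold <= 0) efold <- Inf
  warnf("marker-decay fit did not converge; using log-linear fallback")
  new_fit(exp(coef(ll)[[1L]]), efold, 0, FALSE, fallback = TRUE)
}

#' Evaluate a fitted marker-decay flux model
#'
#' @param object a `decay_fit`.
#' @param t times in seconds.
#' @param ... unused.
#' @return predicted total flux at `t`.
#' @export
predict.decay_fit <- function(object, t, ...) {
  decay <- if (is.finite(object$efold_time)) exp(-t / object$efold_time) else rep(1, length(t))
  object$amplitude * decay + object$offset
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> flux(t) = %.6g * exp(-t / %.6g s) + %.6g  [%d frames%s]\n",
              x$amplitude, x$efold_time, x$offset, length(x$fitted_range),
              if (isTRUE(x$fallback)) ", log-linear fallback" else ""))
  invisible(x)
}

#' Flatten the marker-decay trend of a ratio sequence
#'
#' Multiplies each ratio frame at time `t` by `flux(0) / flux(t)` from the
#' fitted pre-stimulus decay model, extrapolated over the whole sequence.
#'
#' @param ratio_seq a ratio-labeled [frame_sequence()].
#' @param fit a `decay_fit` from [fit_marker_decay()].
#' @return the corrected sequence.
#' @export
correct_marker_decay <- function(ratio_seq, fit) {
  stopifnot(inherits(ratio_seq, "frame_sequence"), inherits(fit, "decay_fit"))
  t <- channel_times(ratio_seq, "ratio")
  fl <- predict(fit, t)
  if (any(fl <= 0))
    stopf("fitted flux is non-positive inside the sequence span; correction refused")
  factor <- predict(fit, 0) / fl
  for (i in seq_along(factor))
    ratio_seq$frames[, , i] <- ratio_seq$frames[, , i] * factor[i]
  ratio_seq$decay_fit <- fit
  ratio_seq
}

#' Estimate the basal (pre-stimulus) ratio image
#'
#' Averages the pre-stimulus ratio frames per pixel after one sigma-reject
#' pass: across frames, values falling outside the `sigma`-standard-
#' deviation band about the per-pixel mean are discarded and the mean is
#' recomputed over the survivors.  The spread is the population standard
#' deviation over frames; if every value at a pixel is rejected the
#' unclipped mean is used.
#'
#' @param ratio_seq a ratio-labeled [frame_sequence()].
#' @param stimulus_frame 1-based first post-stimulus ratio frame index;
#'   defaults to the sequence metadata.
#' @param sigma rejection band half-width in standard deviations.
#' @return a 2-D basal ratio matrix.
#' @export
estimate_basal <- function(ratio_seq, stimulus_frame = NULL, sigma = 2) {
  stopifnot(inherits(ratio_seq, "frame_sequence"))
  stimulus_frame <- stimulus_frame %||% ratio_seq$stimulus_frame
  n_pre <- stimulus_frame - 1L
  if (n_pre < 1L) stopf("no pre-stimulus ratio frames")
  pre <- ratio_seq$frames[, , seq_len(n_pre), drop = FALSE]
  if (n_pre == 1L) {
    warnf("single basal frame: returned as-is, no sigma rejection possible")
    return(pre[, , 1L])
  }
  sigma_clip_mean(pre, sigma)
}

# per-pixel clip-then-mean over the 3rd dimension of a stack; survivors are
# values strictly inside mean +/- sigma * population-sd (constant series
# keep everything)
sigma_clip_mean <- function(stack, sigma) {
  d <- dim(stack)
  n <- d[3L]
  flat <- matrix(stack, d[1L] * d[2L], n)
  m <- rowMeans(flat)
  s <- sqrt(rowMeans((flat - m)^2))
  if (is.finite(sigma)) {
    keep <- abs(flat - m) < sigma * s
    keep[s == 0, ] <- TRUE
    kn <- rowSums(keep)
    clipped <- rowSums(flat * keep) / kn
    clipped[kn == 0] <- m[kn == 0]       # all rejected: unclipped mean
  } else {
    clipped <- m
  }
  matrix(clipped, d[1L], d[2L])
}

#' Extract the calcium wave above basal and its per-pixel statistics
#'
#' Subtracts the basal image from every ratio frame, truncates negatives to
#' zero (only released calcium is of interest; negative excursions are
#' noise), and median-filters each frame to suppress ratio-amplified noise
#' while preserving small structures.  Per-pixel statistics are then
#' computed over the filtered stack: maximum, time of maximum (seconds,
#' earliest in case of ties), mean and standard deviation.
#'
#' @param ratio_seq a ratio-labeled [frame_sequence()] (decay-corrected).
#' @param basal 2-D basal matrix from [estimate_basal()].
#' @param median_kernel odd kernel size 1, 3 or 5 (1 disables filtering).
#' @return an object of class `calibrated_wave`: the non-negative `wave`
#'   stack, `basal`, `stats` (list of the four per-pixel maps), timing
#'   metadata, and any decay fit / registration shifts carried by the
#'   input.
#' @export
extract_wave <- function(ratio_seq, basal, median_kernel = 3L) {
  stopifnot(inherits(ratio_seq, "frame_sequence"), is.matrix(basal))
  if (!all(dim(basal) == dim(ratio_seq$frames)[1:2]))
    stopf("basal shape does not match the frames")
  n <- dim(ratio_seq$frames)[3L]
  wave <- array(0, dim = dim(ratio_seq$frames))
  for (i in seq_len(n))
    wave[, , i] <- median_filter(pmax(ratio_seq$frames[, , i] - basal, 0),
                                 median_kernel)
  d <- dim(wave)
  flat <- matrix(wave, d[1L] * d[2L], n)
  imax <- max.col(flat, ties.method = "first")
  stats <- list(
    maximum = matrix(flat[cbind(seq_len(nrow(flat)), imax)], d[1L], d[2L]),
    t_max = matrix((imax - 1L) * ratio_seq$frame_period, d[1L], d[2L]),
    mean = matrix(rowMeans(flat), d[1L], d[2L]),
    sd = matrix(apply(flat, 1L, sd), d[1L], d[2L])
  )
  structure(list(wave = wave, basal = basal, stats = stats,
                 frame_period = ratio_seq$frame_period,
                 stimulus_frame = ratio_seq$stimulus_frame,
                 pixel_size = ratio_seq$pixel_size,
                 decay_fit = ratio_seq$decay_fit,
                 shifts = ratio_seq$shifts,
                 median_kernel = median_kernel),
            class = "calibrated_wave")
}

#' @export
print.calibrated_wave <- function(x, ...) {
  d <- dim(x$wave)
  cat(sprintf("<calibrated_wave> %d frames of %d x %d px (period %.4g s)\n",
              d[3L], d[1L], d[2L], x$frame_period))
  cat(sprintf("  peak ratio excess %.4g, basal ratio median %.4g\n",
              max(x$stats$maximum), median(x$basal)))
  invisible(x)
}

#' @describeIn calibrate image panels of the four per-pixel statistics.
#' @export
plot.calibrated_wave <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  titles <- c(maximum = "maximum", t_max = "time of maximum (s)",
              mean = "mean", sd = "standard deviation")
  for (nm in names(titles)) {
    graphics::image(t(x$stats[[nm]])[, nrow(x$stats[[nm]]):1],
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    main = titles[[nm]], ...)
  }
  invisible(x)
}

#' Full calibration of a raw interlaced sequence
#'
#' Runs the calibration chain: rigid frame registration (phase correlation
#' on the starlet detail layer), 340:380 ratio computation, marker-decay
#' fitting on pre-stimulus flux and multiplicative correction, sigma-reject
#' basal estimation, and wave extraction with per-pixel statistics.
#'
#' @param seq a raw two-filter [frame_sequence()].
#' @param keep_scale starlet detail scale for registration (1 or 2 px).
#' @param sigma sigma-reject band for the basal estimate.
#' @param median_kernel median-filter kernel (1, 3 or 5).
#' @param register,decay_correct logical switches for the respective
#'   stages.
#' @param eps ratio division guard.
#' @return a `calibrated_wave` (see [extract_wave()]).
#' @export
calibrate <- function(seq, keep_scale = 1L, sigma = 2, median_kernel = 3L,
                      register = TRUE, decay_correct = TRUE, eps = 1e-6) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (register) seq <- align_sequence(seq, keep_scale = keep_scale)
  ratio <- compute_ratio(seq, eps = eps)
  if (decay_correct) {
    fit <- fit_marker_decay(ratio)
    ratio <- correct_marker_decay(ratio, fit)
  }
  basal <- estimate_basal(ratio, sigma = sigma)
  extract_wave(ratio, basal, median_kernel = median_kernel)
}
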