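# Single-filter (380 nm only) fast-velocity mode.
#
# Skipping the 340 nm exposure and the filter-wheel rotation allows a much
# higher sampling rate, improving the temporal resolution of the wave-front
# estimate.  Fura-2 380 nm emission *falls* as calcium binds, so the wave is
# extracted as basal - frame; the 380 nm level is not a calcium index, hence
# only the maximum-gradient (wave-front) velocity is meaningful here.

#' Extract the wave from a single 380 nm stream
#'
#' Applies the two-filter characterization chain without the ratio step:
#' rigid registration, marker-decay flattening fitted on pre-stimulus
#' frames, sigma-reject basal estimation, then
#' `wave = median_filter(max(basal - frame, 0))` -- the sign is inverted so
#' released calcium appears as positive signal.
#'
#' @param seq380 a [frame_sequence()] whose frames are all labeled
#'   `"380"` or `"single"`.
#' @param sigma sigma-reject band for the basal estimate.
#' @param median_kernel median-filter kernel (1, 3 or 5).
#' @param register,decay_correct stage switches; decay correction is
#'   applied by default for symmetry with the two-filter mode.
#' @param keep_scale starlet detail scale for registration.
#' @return a `calibrated_wave` additionally classed `single_filter_wave`.
#' @export
extract_wave_single <- function(seq380, sigma = 2, median_kernel = 3L,
                                register = TRUE, decay_correct = TRUE,
                                keep_scale = 1L) {
  stopifnot(inherits(seq380, "frame_sequence"))
  if (!all(seq380$channels %in% c("380", "single")))
    stopf("single-filter extraction needs a pure 380 nm (or 'single') stream")
  if (register) seq380 <- align_sequence(seq380, keep_scale = keep_scale)
  if (decay_correct) {
    fit <- fit_marker_decay(seq380)
    seq380 <- correct_marker_decay(seq380, fit)
  }
  basal <- estimate_basal(seq380, sigma = sigma)
  n <- dim(seq380$frames)[3L]
  inverted <- seq380
  for (i in seq_len(n))                     # 380 nm falls with bound calcium
    inverted$frames[, , i] <- basal - seq380$frames[, , i]
  wave <- extract_wave(inverted, matrix(0, nrow(basal), ncol(basal)),
                       median_kernel = median_kernel)
  wave$basal <- basal
  class(wave) <- c("single_filter_wave", class(wave))
  wave
}

#' Wave-front velocity from a single-filter wave
#'
#' Ring-reduces the single-filter wave and fits the maximum-gradient
#' velocity.  The `max_intensity` mode is refused: 380 nm intensity maxima
#' are not correlated with the maximum calcium concentration, so velocities
#' derived from them are unreliable in this mode.
#'
#' @param wave a `single_filter_wave` from [extract_wave_single()].
#' @param source `c(row, col)` propagation origin.
#' @param max_radius largest radius (px) to sample.
#' @param mask optional mask.
#' @param mode must be `"max_gradient"`.
#' @inheritParams velocity_fit
#' @return a `robust_lm` with velocity fields, as [velocity_fit()].
#' @export
single_filter_velocity <- function(wave, source, max_radius, mask = NULL,
                                   mode = "max_gradient", clip_sigma = 2,
                                   max_iter = 5L) {
  stopifnot(inherits(wave, "single_filter_wave"))
  if (!identical(mode, "max_gradient"))
    stopf(paste("mode '%s' is not supported for single-filter data:",
                "380 nm intensity maxima do not track the calcium maximum;",
                "use mode = 'max_gradient'"), mode)
  map <- ring_profile(wave, source = source, max_radius = max_radius, mask = mask)
  velocity_fit(map, mode = "max_gradient", clip_sigma = clip_sigma,
               max_iter = max_iter)
}
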