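# Fourier phase-correlation registration of frames.

#' Estimate the integer translation between two frames
#'
#' Both images are reduced to their pixel-scale starlet detail layer (see
#' [starlet_prefilter()]) so that frames taken through different filters
#' become comparable, then the whole-pixel translation is read off the peak
#' of the Fourier phase-correlation surface.  The returned shift `c(dy, dx)`
#' is the displacement of `target` relative to `reference`: applying the
#' negated shift to `target` (e.g. with [shift_matrix()]) aligns it to
#' `reference`.
#'
#' @param reference,target numeric matrices of identical shape.
#' @param keep_scale starlet detail scale used for prefiltering (1 or 2).
#' @param prefilter set to `FALSE` to correlate the raw intensities
#'   (e.g. for same-channel pairs already on one intensity scale).
#' @return integer vector `c(dy, dx)`; shifts are reported in
#'   `(-n/2, n/2]` per axis.  If either prefiltered image is identically
#'   zero the shift is `c(0, 0)` with attribute `flat = TRUE` and a warning.
#' @export
register_translation <- function(reference, target, keep_scale = 1L,
                                 prefilter = TRUE) {
  stopifnot(is.matrix(reference), is.matrix(target))
  if (!all(dim(reference) == dim(target)))
    stopf("reference and target must have the same shape")
  a <- if (prefilter) starlet_prefilter(reference, keep_scale) else reference
  b <- if (prefilter) starlet_prefilter(target, keep_scale) else target
  if (all(a == 0) || all(b == 0)) {
    warnf("featureless image(s): registration returned a zero shift")
    out <- c(0L, 0L)
    attr(out, "flat") <- TRUE
    return(out)
  }
  fa <- fft(a)
  fb <- fft(b)
  cross <- fb * Conj(fa)
  mag <- Mod(cross)
  cross <- cross / pmax(mag, .Machine$double.eps)
  surf <- Re(fft(cross, inverse = TRUE)) / length(cross)
  peak <- arrayInd(which.max(surf), dim(surf))
  wrap <- function(p, n) if (p - 1L > n %/% 2L) p - 1L - n else p - 1L
  c(wrap(peak[1L], nrow(surf)), wrap(peak[2L], ncol(surf)))
}

#' Rigidly align an interlaced sequence to its first frame
#'
#' Every frame is registered against the first frame of the sequence and
#' shifted back by whole pixels (edge rows/columns replicated).  Cross-filter
#' comparability is provided by the wavelet prefilter inside
#' [register_translation()].
#'
#' @param seq a [frame_sequence()].
#' @param keep_scale starlet detail scale for the prefilter.
#' @return `seq` with aligned frames and the per-frame estimated shifts
#'   attached as `seq$shifts` (a `n_frames x 2` integer matrix of
#'   `(dy, dx)`).
#' @export
align_sequence <- function(seq, keep_scale = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- dim(seq$frames)[3L]
  shifts <- matrix(0L, n, 2L, dimnames = list(NULL, c("dy", "dx")))
  ref <- seq$frames[, , 1L]
  for (i in seq_len(n)[-1L]) {
    s <- register_translation(ref, seq$frames[, , i], keep_scale = keep_scale)
    shifts[i, ] <- s
    if (any(s != 0L))
      seq$frames[, , i] <- shift_matrix(seq$frames[, , i], -s)
  }
  seq$shifts <- shifts
  seq
}
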