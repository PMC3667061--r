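# Starlet (a-trous) isotropic undecimated wavelet transform.
#
# Successive smoothings use the separable B3-spline kernel
# [1, 4, 6, 4, 1] / 16 with holes of 2^(j-1) pixels at scale j; the detail
# (wavelet) layer at scale j is the difference of consecutive smoothings, so
# the input is exactly the sum of all detail layers plus the last smooth.
# Boundaries are mirrored.

b3_weights <- c(1, 4, 6, 4, 1) / 16

# reflect out-of-range 1-based indices back into 1..n (mirror boundary)
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  i <- ifelse(i >= n, p - i, i)
  i + 1L
}

# one separable B3-spline smoothing pass with hole spacing `step`
atrous_smooth <- function(m, step) {
  offs <- c(-2L, -1L, 0L, 1L, 2L) * step
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(offs))  # rows
    out <- out + b3_weights[k] * m[mirror_index(seq_len(nrow(m)) + offs[k], nrow(m)), , drop = FALSE]
  res <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(offs))  # columns
    res <- res + b3_weights[k] * out[, mirror_index(seq_len(ncol(m)) + offs[k], ncol(m)), drop = FALSE]
  res
}

#' Starlet wavelet decomposition of an image
#'
#' Decomposes an image into `n_scales` detail layers plus a residual smooth
#' image.  Layer `j` carries structures of characteristic size about
#' `2^(j-1)` pixels; summing all layers and the smooth reconstructs the
#' input exactly.
#'
#' @param image a numeric matrix.
#' @param n_scales number of detail layers to extract.
#' @return a list with elements `details` (list of matrices, finest first)
#'   and `smooth` (the final smoothed image).
#' @export
starlet_transform <- function(image, n_scales = 2L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (!is_count(n_scales) || n_scales < 1L) stopf("n_scales must be a positive integer")
  details <- vector("list", n_scales)
  current <- image
  for (j in seq_len(n_scales)) {
    smooth <- atrous_smooth(current, 2L^(j - 1L))
    details[[j]] <- current - smooth
    current <- smooth
  }
  list(details = details, smooth = current)
}

#' Wavelet prefilter retaining one small-scale detail layer
#'
#' Keeps only the starlet detail layer of 1 px or 2 px characteristic scale
#' and max-min rescales it to \[0, 1\].  Frames taken through different
#' excitation filters have incompatible intensity mappings; their
#' pixel-scale structure, isolated this way, is comparable across channels
#' and is what the registration stage correlates.
#'
#' @param image a numeric matrix.
#' @param keep_scale which detail layer to keep: 1 (1-px structures) or 2.
#' @return a matrix in \[0, 1\]; identically zero when the retained layer is
#'   constant (e.g. for a constant input image).
#' @export
starlet_prefilter <- function(image, keep_scale = 1L) {
  if (!is_count(keep_scale) || !(keep_scale %in% c(1L, 2L)))
    stopf("keep_scale must be 1 or 2")
  w <- starlet_transform(image, n_scales = keep_scale)$details[[keep_scale]]
  rescale01(w)
}
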