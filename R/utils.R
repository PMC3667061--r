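# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x)

#' Circularly roll a matrix
#'
#' Shifts a matrix by whole pixels with wrap-around, so that
#' `roll_matrix(m, c(dy, dx))[i, j] == m[i - dy, j - dx]` (indices modulo the
#' matrix extent).
#'
#' @param m a numeric matrix.
#' @param shift integer `c(dy, dx)`; positive values move content down/right.
#' @return the rolled matrix.
#' @export
roll_matrix <- function(m, shift) {
  stopifnot(is.matrix(m), length(shift) == 2L)
  dy <- as.integer(round(shift[1L])) %% nrow(m)
  dx <- as.integer(round(shift[2L])) %% ncol(m)
  if (dy != 0L) m <- m[c((nrow(m) - dy + 1L):nrow(m), seq_len(nrow(m) - dy)), , drop = FALSE]
  if (dx != 0L) m <- m[, c((ncol(m) - dx + 1L):ncol(m), seq_len(ncol(m) - dx)), drop = FALSE]
  m
}

#' Translate a matrix with edge replication
#'
#' Shifts content by whole pixels; rows/columns exposed at the borders are
#' filled by replicating the nearest edge, so no wrap-around artifacts enter
#' the frame.
#'
#' @inheritParams roll_matrix
#' @return the shifted matrix.
#' @export
shift_matrix <- function(m, shift) {
  stopifnot(is.matrix(m), length(shift) == 2L)
  dy <- as.integer(round(shift[1L]))
  dx <- as.integer(round(shift[2L]))
  ri <- pmin(pmax(seq_len(nrow(m)) - dy, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) - dx, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# max-min rescale to [0, 1]; degenerate (constant) input maps to all zeros
rescale01 <- function(m) {
  r <- range(m, finite = TRUE)
  if (!is.finite(r[1L]) || r[2L] - r[1L] <= 0) {
    m[] <- 0
    return(m)
  }
  (m - r[1L]) / (r[2L] - r[1L])
}

# Euclidean distance of every pixel to a (row, col) point, as a matrix
distance_map <- function(nrow, ncol, point) {
  dr <- seq_len(nrow) - point[1L]
  dc <- seq_len(ncol) - point[2L]
  sqrt(outer(dr^2, dc^2, `+`))
}

# 2-D median filter on an arbitrary-range matrix.  EBImage's constant-time
# median filter operates on [0, 1] data, so rescale around it; kernel = 1 is
# the identity.
median_filter <- function(m, kernel = 3L) {
  if (!is_count(kernel) || !(kernel %in% c(1L, 3L, 5L)))
    stopf("median kernel must be 1, 3 or 5 (odd, <= 5); got %s", format(kernel))
  if (kernel == 1L) return(m)
  r <- range(m, finite = TRUE)
  if (r[2L] - r[1L] <= 0) return(m)
  scaled <- (m - r[1L]) / (r[2L] - r[1L])
  out <- EBImage::medianFilter(scaled, size = (kernel - 1L) %/% 2L)
  as.matrix(out) * (r[2L] - r[1L]) + r[1L]
}
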