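# Minimal FITS image I/O (32-bit IEEE float, single image HDU).
#
# Calibrated outputs are stored as 32-bit floating-point FITS so downstream
# tools keep full numerical accuracy.  No FITS library is available in this
# R stack, so the small subset of the standard needed here -- SIMPLE image
# HDUs with BITPIX = -32, 2-D or 3-D -- is implemented directly: 80-character
# header cards in 2880-byte blocks followed by big-endian float data padded
# to a block boundary.  Axis 1 is the R row index.

fits_card <- function(key, value = NULL, comment = NULL) {
  if (is.null(value)) {
    card <- key
  } else {
    v <- if (is.logical(value)) {
      sprintf("%20s", ifelse(value, "T", "F"))
    } else if (is.character(value)) {
      sprintf("%-20s", sprintf("'%s'", value))
    } else if (is.numeric(value) && value == round(value) && abs(value) < 2^31) {
      sprintf("%20d", as.integer(value))
    } else {
      sprintf("%20.10E", value)
    }
    card <- sprintf("%-8s= %s", key, v)
    if (!is.null(comment)) card <- paste0(card, " / ", comment)
  }
  substr(sprintf("%-80s", card), 1L, 80L)
}

fits_pad <- function(n) (2880L - (n %% 2880L)) %% 2880L

#' Write an image to a 32-bit float FITS file
#'
#' @param x a numeric matrix or 3-D array.
#' @param path output file path.
#' @param extra_keys optional named list of scalar header keywords
#'   (logical, numeric or short character values).
#' @return `path`, invisibly.
#' @seealso [read_fits()]
#' @export
write_fits <- function(x, path, extra_keys = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  naxis <- if (d[3L] == 1L) 2L else 3L
  cards <- c(
    fits_card("SIMPLE", TRUE, "minimal FITS image"),
    fits_card("BITPIX", -32L, "IEEE 32-bit float"),
    fits_card("NAXIS", naxis),
    fits_card("NAXIS1", d[1L]),
    fits_card("NAXIS2", d[2L])
  )
  if (naxis == 3L) cards <- c(cards, fits_card("NAXIS3", d[3L]))
  for (k in names(extra_keys)) {
    if (nchar(k) > 8L) stopf("FITS keyword too long: %s", k)
    cards <- c(cards, fits_card(toupper(k), extra_keys[[k]]))
  }
  cards <- c(cards, fits_card("END"))
  hdr <- paste(cards, collapse = "")
  hdr <- paste0(hdr, strrep(" ", fits_pad(nchar(hdr))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  vals <- as.numeric(x)
  vals[!is.finite(vals)] <- NaN
  writeBin(vals, con, size = 4L, endian = "big")
  npad <- fits_pad(4L * length(vals))
  if (npad > 0L) writeBin(raw(npad), con)
  invisible(path)
}

#' Read a 32-bit float FITS image written by [write_fits()]
#'
#' @param path file path.
#' @return a matrix (2-D image) or 3-D array, with scalar header keywords
#'   beyond the structural ones attached as the `"keys"` attribute.
#' @export
read_fits <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  cards <- character(0)
  repeat {
    block <- readChar(con, 2880L, useBytes = TRUE)
    if (nchar(block) < 2880L) stopf("truncated FITS header in %s", path)
    cards <- c(cards, substring(block, seq(1L, 2880L, 80L), seq(80L, 2880L, 80L)))
    if (any(grepl("^END +$", cards))) break
  }
  cards <- cards[seq_len(which(grepl("^END +$", cards))[1L] - 1L)]
  key <- toupper(trimws(substr(cards, 1L, 8L)))
  has_val <- substr(cards, 9L, 10L) == "= "
  raw_val <- sub("/.*$", "", substr(cards, 11L, 80L))
  parse_val <- function(v) {
    v <- trimws(v)
    if (v %in% c("T", "F")) return(v == "T")
    if (grepl("^'.*'$", v)) return(trimws(gsub("^'|'$", "", v)))
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  }
  keys <- setNames(lapply(raw_val[has_val], parse_val), key[has_val])
  if (!isTRUE(keys$SIMPLE) || keys$BITPIX != -32)
    stopf("%s: only SIMPLE BITPIX=-32 FITS images are supported", path)
  naxis <- as.integer(keys$NAXIS)
  d <- vapply(seq_len(naxis), function(i) as.integer(keys[[paste0("NAXIS", i)]]), 1L)
  n <- prod(d)
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "big")
  if (length(vals) < n) stopf("truncated FITS data in %s", path)
  out <- if (naxis == 2L) matrix(vals, d[1L], d[2L]) else array(vals, d)
  keys <- keys[!names(keys) %in%
                 c("SIMPLE", "BITPIX", "NAXIS", paste0("NAXIS", seq_len(naxis)))]
  if (length(keys)) attr(out, "keys") <- keys
  out
}
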