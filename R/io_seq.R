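# Frame-sequence container and raw/calibrated I/O.

#' Construct a frame sequence
#'
#' The container for a time-ordered stack of single-channel frames.
#' Intensities are stored as fractions of full scale (doubles in \[0, 1\]
#' for raw data; ratio frames may exceed 1).  In two-filter mode channels
#' strictly alternate 340, 380, 340, ...  Time of same-channel frame `i`
#' (1-based) is `(i - 1) * frame_period` seconds; a ratio frame inherits the
#' time of its 340 nm frame.
#'
#' @param frames a 3-D array `rows x cols x n_frames`, or a list of
#'   matrices of one shape.
#' @param channels per-frame channel label: `"340"`, `"380"`, `"ratio"` or
#'   `"single"`; a single value is recycled.
#' @param frame_period seconds between consecutive same-channel exposures.
#' @param stimulus_frame 1-based index (in same-channel numbering) of the
#'   first post-stimulus frame.
#' @param pixel_size physical pixel pitch in micrometres per pixel.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, channels, frame_period, stimulus_frame,
                           pixel_size = 1.025) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L) stopf("all frames must share one shape")
    frames <- array(unlist(frames), dim = c(shapes[[1L]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  n <- dim(frames)[3L]
  channels <- as.character(rep_len(channels, n))
  bad <- setdiff(unique(channels), c("340", "380", "ratio", "single"))
  if (length(bad)) stopf("unknown channel label(s): %s", paste(bad, collapse = ", "))
  if (all(c("340", "380") %in% channels)) {
    expect <- rep_len(c("340", "380"), n)
    if (!identical(channels, expect))
      stopf("two-filter sequences must strictly alternate 340/380 starting at 340")
  }
  if (!is.numeric(frame_period) || frame_period <= 0)
    stopf("frame_period must be > 0 seconds")
  n_same <- if (all(c("340", "380") %in% channels)) sum(channels == "340") else n
  # stimulus_frame = n_same + 1 denotes an all-basal (pre-stimulus) sequence
  if (!is_count(stimulus_frame) || stimulus_frame < 1L || stimulus_frame > n_same + 1L)
    stopf("stimulus_frame must be an index in 1..%d", n_same + 1L)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0 um/px")
  structure(list(frames = frames, channels = channels,
                 frame_period = frame_period,
                 stimulus_frame = as.integer(stimulus_frame),
                 pixel_size = pixel_size),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %d x %d px\n", d[3L], d[1L], d[2L]))
  cat(sprintf("  channels: %s\n", paste(unique(x$channels), collapse = "/")))
  cat(sprintf("  frame period %.4g s, stimulus frame %d, pixel size %.4g um/px\n",
              x$frame_period, x$stimulus_frame, x$pixel_size))
  invisible(x)
}

n_channel_frames <- function(seq, channel) sum(seq$channels == channel)

# acquisition times (s) of the frames carrying `channel`
channel_times <- function(seq, channel = c("ratio", "340", "380", "single")) {
  channel <- match.arg(channel)
  n <- sum(seq$channels == channel)
  (seq_len(n) - 1L) * seq$frame_period
}

#' Read a raw interlaced TIFF frame sequence
#'
#' Loads numbered single-frame grayscale TIFF files (8- or 16-bit) in
#' lexicographic order and rescales them to \[0, 1\] by the container's full
#' scale.
#'
#' @param path a directory containing the frames, or a vector of file
#'   paths, or a glob pattern.
#' @param channel_rule how to assign a channel to each file:
#'   `"filename"` looks for a `"340"` / `"380"` token in the file name,
#'   `"alternating"` labels odd files 340 and even files 380 in load order,
#'   `"single"` labels everything 380 (one-filter mode).
#' @inheritParams frame_sequence
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, channel_rule = c("filename", "alternating", "single"),
                          frame_period, stimulus_frame, pixel_size = 1.025) {
  channel_rule <- match.arg(channel_rule)
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.tiff?$", full.names = TRUE, ignore.case = TRUE)
  } else if (length(path) == 1L && grepl("[*?]", path)) {
    Sys.glob(path)
  } else {
    path
  }
  files <- sort(files)
  if (length(files) == 0L) stopf("no TIFF files found for %s", paste(path, collapse = ", "))
  missing <- files[!file.exists(files)]
  if (length(missing)) stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  mats <- lapply(files, function(f) {
    m <- tiff::readTIFF(f)             # readTIFF rescales by full scale
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate replicated-channel gray
    m
  })
  shapes <- unique(lapply(mats, dim))
  if (length(shapes) != 1L)
    stopf("frames have mixed shapes: %s",
          paste(vapply(shapes, paste, "", collapse = "x"), collapse = " vs "))
  channels <- switch(channel_rule,
    filename = {
      base <- basename(files)
      has340 <- grepl("340", base)
      has380 <- grepl("380", base)
      if (any(has340 & has380) || any(!has340 & !has380))
        stopf("channel_rule='filename' could not label every file by a 340/380 token")
      ifelse(has340, "340", "380")
    },
    alternating = rep_len(c("340", "380"), length(files)),
    single = rep("380", length(files))
  )
  frame_sequence(mats, channels, frame_period = frame_period,
                 stimulus_frame = stimulus_frame, pixel_size = pixel_size)
}

#' Write named images as 32-bit FITS files with a manifest
#'
#' Each named 2-D or 3-D grid is saved as a 32-bit floating-point FITS file
#' (full numerical accuracy); a plain-text manifest maps names to files.
#'
#' @param images a named list of matrices / 3-D arrays.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a data frame with columns `name` and `file`; also
#'   written to `manifest.txt` in `out_dir`.
#' @export
write_outputs <- function(images, out_dir) {
  stopifnot(is.list(images))
  if (length(images) && (is.null(names(images)) || any(names(images) == "")))
    stopf("every image must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(images))
  for (i in seq_along(images)) {
    f <- file.path(out_dir, paste0(names(images)[i], ".fits"))
    tryCatch(write_fits(images[[i]], f),
             error = function(e) stopf("failed writing %s: %s", f, conditionMessage(e)))
    files[i] <- f
  }
  manifest <- data.frame(name = names(images) %||% character(0), file = files,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
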