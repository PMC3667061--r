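# Global analysis: source localization, radial ring reduction, robust
# linear velocity fits, and decay-model fitting per radial distance.

#' Locate the propagation source automatically
#'
#' Works on the wave image at the stimulus frame.  The image is opened with
#' a 3 x 3 grayscale erosion-then-dilation to suppress noise, linearly
#' rescaled to \[0, 1\], and soft-thresholded (values below `threshold` set
#' to zero).  The intensity-weighted center of mass is then refined
#' iteratively: each iteration halves the window per dimension, recentered
#' on the previous center of mass, until the next window would fall below
#' `min_window` pixels in either dimension.  This homes in on the biggest
#' and brightest structure, so secondary calcium releases or noise do not
#' drag the estimate.
#'
#' @param stimulus_image 2-D wave image at (or just after) the stimulus
#'   frame.
#' @param threshold normalized soft-threshold level.
#' @param min_window smallest window side (px) of the iteration.
#' @return `c(row, col)` of the source, rounded to the nearest pixel.
#'   Fails with an error if nothing survives thresholding (the operator may
#'   then supply manual coordinates downstream).
#' @export
find_source <- function(stimulus_image, threshold = 0.2, min_window = 20L) {
  stopifnot(is.matrix(stimulus_image), all(is.finite(stimulus_image)))
  box <- EBImage::makeBrush(3L, shape = "box")
  img <- as.matrix(EBImage::dilate(EBImage::erode(stimulus_image, box), box))
  img <- rescale01(img)
  img[img < threshold] <- 0
  if (all(img == 0))
    stopf("no source found: image is empty after thresholding (supply coordinates manually)")
  nr <- nrow(img); nc <- ncol(img)
  win <- c(nr, nc)                        # current window extent
  center <- c((1 + nr) / 2, (1 + nc) / 2)
  repeat {
    r0 <- max(1L, ceiling(center[1L] - win[1L] / 2))
    r1 <- min(nr, floor(center[1L] + win[1L] / 2))
    c0 <- max(1L, ceiling(center[2L] - win[2L] / 2))
    c1 <- min(nc, floor(center[2L] + win[2L] / 2))
    sub <- img[r0:r1, c0:c1, drop = FALSE]
    tot <- sum(sub)
    if (tot > 0) {
      rows <- r0:r1; cols <- c0:c1
      center <- c(sum(rows * rowSums(sub)), sum(cols * colSums(sub))) / tot
    }
    if (any(win / 2 < min_window)) break
    win <- win / 2
  }
  round(center)
}

#' Reduce a wave stack to a radial-distance/time map
#'
#' Assuming radial symmetry about the source, pixels are grouped into
#' concentric one-pixel-wide rings (half-open Euclidean bins
#' `r <= dist < r + 1`) and averaged per ring and frame.  Row `t`, column
#' `r + 1` of the result holds the mean wave value at radius `r` px at the
#' `t`-th ratio frame; this radial-time image is what the velocity and
#' model fits consume.
#'
#' @param wave a `calibrated_wave` or a 3-D wave stack.
#' @param source `c(row, col)` of the propagation origin.
#' @param max_radius largest radius (px) to sample; clipped (with a
#'   warning) to the largest ring fully measurable from the source.
#' @param mask optional [build_mask()] result or 0/1 matrix; when given,
#'   ring means use masked-on pixels only.
#' @param frame_period,pixel_size timing metadata; taken from `wave` when
#'   it is a `calibrated_wave`.
#' @return an object of class `radial_time_map`: `values`
#'   (time x radius matrix, `NA` for empty rings), `counts`, `source`,
#'   `frame_period`, `pixel_size`.
#' @export
ring_profile <- function(wave, source, max_radius, mask = NULL,
                         frame_period = NULL, pixel_size = NULL) {
  if (inherits(wave, "calibrated_wave")) {
    frame_period <- frame_period %||% wave$frame_period
    pixel_size <- pixel_size %||% wave$pixel_size
    stack <- wave$wave
  } else {
    stack <- wave
    frame_period <- frame_period %||% 1
    pixel_size <- pixel_size %||% 1.025
  }
  stopifnot(length(dim(stack)) == 3L, length(source) == 2L)
  d <- dim(stack)
  if (any(source < 1) || source[1L] > d[1L] || source[2L] > d[2L])
    stopf("source must lie inside the frame")
  if (!is.numeric(max_radius) || max_radius < 2) stopf("max_radius must be >= 2")
  r_fit <- floor(min(source[1L] - 1, d[1L] - source[1L],
                     source[2L] - 1, d[2L] - source[2L]))
  if (max_radius > r_fit + 1) {
    warnf("max_radius %g exceeds the frame bounds; clipped to %d", max_radius, r_fit + 1)
    max_radius <- r_fit + 1
  }
  max_radius <- as.integer(floor(max_radius))
  dist <- distance_map(d[1L], d[2L], source)
  keep <- as_mask_matrix(mask, d[1:2]) & (dist < max_radius)
  ring <- floor(dist)[keep] + 1L          # ring r: r <= dist < r+1 -> bin r+1
  flat <- matrix(stack, d[1L] * d[2L], d[3L])[as.vector(keep), , drop = FALSE]
  counts <- tabulate(ring, nbins = max_radius)
  sums <- rowsum(flat, group = ring, reorder = TRUE)
  values <- matrix(NA_real_, d[3L], max_radius)
  present <- sort(unique(ring))
  values[, present] <- t(sums / counts[present])
  structure(list(values = values, counts = counts, source = source,
                 frame_period = frame_period, pixel_size = pixel_size),
            class = "radial_time_map")
}

#' @export
print.radial_time_map <- function(x, ...) {
  cat(sprintf("<radial_time_map> %d frames x %d radial bins, source (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$source[1L], x$source[2L]))
  invisible(x)
}

#' @export
plot.radial_time_map <- function(x, ...) {
  v <- x$values
  v[is.na(v)] <- 0
  graphics::image(x = (seq_len(ncol(v)) - 1L),
                  y = (seq_len(nrow(v)) - 1L) * x$frame_period,
                  z = t(v), col = grDevices::gray.colors(256, 0, 1),
                  xlab = "radial distance (px)", ylab = "time (s)",
                  main = "ring-averaged wave", ...)
  invisible(x)
}

#' Robust linear fit with iterative outlier rejection
#'
#' Ordinary least squares, iterated: fit, compute the residual standard
#' deviation, drop points whose absolute residual exceeds
#' `clip_sigma * sd`, refit; stops when no point is dropped or after
#' `max_iter` passes.  With `clip_sigma = Inf` this is plain OLS.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @param clip_sigma rejection threshold in residual standard deviations.
#' @param max_iter maximum rejection passes.
#' @param mode label describing what is being fitted (carried through to
#'   velocity reporting).
#' @return an object of class `robust_lm`: `slope`, `intercept`,
#'   `r_squared`, `n_used`, `n_rejected`, `mode`, and the surviving `x`,
#'   `y`.
#' @export
robust_linear_fit <- function(x, y, clip_sigma = 2, max_iter = 5L,
                              mode = "linear") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("robust fit needs at least 3 finite points")
  if (diff(range(x)) == 0) stopf("degenerate fit: all x identical")
  keep <- rep(TRUE, length(x))
  # every pass re-evaluates all points against the current fit, so inliers
  # dropped while a gross outlier tilted the line are recovered once it is
  # gone; the band never collapses below a scale-relative floor
  band_floor <- 1e-8 * (diff(range(y)) + .Machine$double.eps)
  for (iter in seq_len(max_iter)) {
    fit <- lm(y[keep] ~ x[keep])
    if (!is.finite(clip_sigma)) break
    res_all <- y - (coef(fit)[[1L]] + coef(fit)[[2L]] * x)
    s <- sd(res_all[keep])
    if (!is.finite(s)) break
    new_keep <- abs(res_all) <= max(clip_sigma * s, band_floor)
    if (sum(new_keep) < 3L || identical(new_keep, keep)) break
    keep <- new_keep
  }
  fit <- lm(y[keep] ~ x[keep])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y[keep] - mean(y[keep]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]],
                 r_squared = max(0, min(1, r2)),
                 n_used = sum(keep), n_rejected = sum(!keep),
                 mode = mode, x = x[keep], y = y[keep]),
            class = "robust_lm")
}

#' @export
coef.robust_lm <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.robust_lm <- function(object, x, ...) object$intercept + object$slope * x

#' @export
print.robust_lm <- function(x, ...) {
  cat(sprintf("<robust_lm:%s> y = %.6g + %.6g x  (R2 %.4f, used %d, rejected %d)\n",
              x$mode, x$intercept, x$slope, x$r_squared, x$n_used, x$n_rejected))
  if (!is.null(x$velocity_px_s))
    cat(sprintf("  velocity %.4g px/s = %.4g um/s\n", x$velocity_px_s, x$velocity_um_s))
  invisible(x)
}

#' @export
plot.robust_lm <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, xlab = "radial distance (px)",
                 ylab = "time (s)", main = sprintf("%s fit", x$mode), ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Wave-front velocity from a radial-time map
#'
#' Per radial bin, finds the time of the maximum ring-averaged value
#' (`mode = "max_intensity"`) or of the maximum positive forward temporal
#' difference (`mode = "max_gradient"`, the wave-front estimator), then
#' regresses time on radius with outlier rejection.  The mean propagation
#' velocity is the inverse slope, reported in px/s and -- via the pixel
#' size -- in um/s.  Ties in the per-bin argmax resolve to the earliest
#' time.
#'
#' @param map a [ring_profile()] result.
#' @param mode `"max_intensity"` or `"max_gradient"`.
#' @param clip_sigma,max_iter passed to [robust_linear_fit()].
#' @return a `robust_lm` with extra fields `velocity_px_s`,
#'   `velocity_um_s` (both `NA` with a `nonphysical = TRUE` flag when the
#'   fitted slope is not positive) and `t_feature` (per-bin feature times).
#' @export
velocity_fit <- function(map, mode = c("max_gradient", "max_intensity"),
                         clip_sigma = 2, max_iter = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "radial_time_map"))
  v <- map$values
  valid <- colSums(is.finite(v)) == nrow(v) & map$counts > 0
  if (sum(valid) < 3L) stopf("fewer than 3 valid radial bins")
  feature <- if (mode == "max_intensity") v else diff(v)
  t_feature <- rep(NA_real_, ncol(v))
  for (j in which(valid))                               # earliest tie wins
    t_feature[j] <- (which.max(feature[, j]) - 1L) * map$frame_period
  r <- seq_len(ncol(v)) - 1L
  fit <- robust_linear_fit(r[valid], t_feature[valid], clip_sigma = clip_sigma,
                           max_iter = max_iter, mode = mode)
  if (fit$slope > 0) {
    fit$velocity_px_s <- 1 / fit$slope
    fit$velocity_um_s <- map$pixel_size / fit$slope
  } else {
    fit$velocity_px_s <- NA_real_
    fit$velocity_um_s <- NA_real_
    fit$nonphysical <- TRUE
  }
  fit$t_feature <- setNames(t_feature, r)
  fit
}

#' Linear decay of the per-radius maximum and the maximum propagation radius
#'
#' Far from the stimulus the maximum ring-averaged intensity decays
#' approximately linearly with radius; extrapolating the robust linear fit
#' to zero intensity estimates the maximum propagation radius.
#'
#' @param map a [ring_profile()] result.
#' @param r_min radius (px) below which bins are excluded (the near-source
#'   region does not follow the linear trend).
#' @inheritParams velocity_fit
#' @return a `robust_lm` (mode `"amplitude_decay"`) with extra field
#'   `zero_crossing_radius` (px; `NA` with `crossing_undefined = TRUE`
#'   when the fitted slope is not negative).
#' @export
amplitude_decay_fit <- function(map, r_min = 10, clip_sigma = 2, max_iter = 5L) {
  stopifnot(inherits(map, "radial_time_map"))
  v <- map$values
  r <- seq_len(ncol(v)) - 1L
  peak <- suppressWarnings(apply(v, 2L, max, na.rm = TRUE))
  sel <- r >= r_min & is.finite(peak)
  if (sum(sel) < 3L) stopf("need at least 3 radial bins beyond r_min")
  fit <- robust_linear_fit(r[sel], peak[sel], clip_sigma = clip_sigma,
                           max_iter = max_iter, mode = "amplitude_decay")
  # the slope must be meaningfully negative: a numerically zero slope on
  # flat maxima gives no crossing
  slope_floor <- 1e-9 * (max(abs(fit$y)) + .Machine$double.eps) /
    max(diff(range(fit$x)), 1)
  if (fit$slope < -slope_floor) {
    fit$zero_crossing_radius <- -fit$intercept / fit$slope
  } else {
    fit$zero_crossing_radius <- NA_real_
    fit$crossing_undefined <- TRUE
  }
  fit
}

#' Heaviside-gated decay models of the local calcium transient
#'
#' Both models describe the ratio excess at one location as zero before the
#' activation time and a decaying pulse afterwards:
#' exponential `f(t) = H(t - t0) A exp(-(t - t0) / tau)` and
#' rational-quadratic `f(t) = H(t - t0) A tau^2 / (tau^2 + (t - t0)^2)`,
#' with `H(0) = 1` (the wave is present at the activation instant).
#'
#' @param params a list/vector with `A`, `t0`, `tau`, or a
#'   `wave_model_fit`.
#' @param t times (s).
#' @param model_kind `"exponential"` or `"quadratic"`; ignored when
#'   `params` carries its own `model_kind`.
#' @return model values at `t`.
#' @export
evaluate_model <- function(params, t, model_kind = c("exponential", "quadratic")) {
  if (!is.null(params$model_kind)) model_kind <- params$model_kind
  model_kind <- match.arg(model_kind)
  A <- params[["A"]]; t0 <- params[["t0"]]; tau <- params[["tau"]]
  if (tau <= 0) stopf("tau must be > 0")
  dt <- t - t0
  gate <- as.numeric(dt >= 0)
  if (model_kind == "exponential") gate * A * exp(-pmax(dt, 0) / tau)
  else gate * A * tau^2 / (tau^2 + dt^2)
}

#' Fit the Heaviside-gated decay model to a time series
#'
#' Levenberg-Marquardt least squares of the exponential (or quadratic)
#' decay model to one non-negative time series (a ring average or a single
#' pixel).  Unless supplied, starting values are: `t0` at the time of the
#' maximum forward difference, `A` at the series maximum, `tau` at a
#' quarter of the post-`t0` span.
#'
#' @param t times (s), same length as `y`.
#' @param y non-negative series values (>= 6 points).
#' @param model_kind `"exponential"` or `"quadratic"`.
#' @param init optional named starting values `c(A=, t0=, tau=)`.
#' @return an object of class `wave_model_fit` with fields `A`, `t0`,
#'   `tau`, `model_kind`, `residual_norm` and `converged`.  An all-zero
#'   series returns the flat `A = 0` fit flagged unconverged.
#'
#' @details For the exponential model an exactly model-consistent series
#' determines only the product `A * exp(t0 / tau)`: every activation time
#' inside the sampling interval bracketing the onset fits the data with
#' zero residual.  When the optimum is degenerate in this sense (relative
#' residual below `1e-6`), the activation time is resolved to the first
#' strictly positive sample -- the time at which the model attains its peak
#' -- and `A` and `tau` are refitted with `t0` held fixed.  Noisy series
#' never trigger this tie-break.
#' @export
fit_decay_model <- function(t, y, model_kind = c("exponential", "quadratic"),
                            init = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(t) == length(y))
  if (length(y) < 6L) stopf("need at least 6 time points")
  if (any(y < 0)) stopf("series must be non-negative")
  new_fit <- function(A, t0, tau, rnorm_, conv)
    structure(list(A = A, t0 = t0, tau = tau, model_kind = model_kind,
                   residual_norm = rnorm_, converged = conv),
              class = "wave_model_fit")
  if (all(y == 0)) return(new_fit(0, t[1L], 1, 0, FALSE))
  if (is.null(init)) {
    # the maximum forward difference marks the onset; take the time at which
    # the rise is realized (one sample later the gate is surely open).  A
    # series already decaying from its first sample has no rise: the series
    # maximum marks the activation instead.
    imax_grad <- which.max(diff(y))
    t0_init <- min(t[min(imax_grad + 1L, length(t))], t[which.max(y)])
    span <- max(t) - t0_init
    init <- c(A = max(y), t0 = t0_init, tau = max(span / 4, diff(range(t)) / 20))
  }
  init <- pmin(pmax(unlist(init)[c("A", "t0", "tau")],
                    c(0, min(t), 1e-6)), c(Inf, max(t), Inf))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = init,
      fn = function(p) y - evaluate_model(list(A = p[1L], t0 = p[2L], tau = p[3L]),
                                          t, model_kind),
      lower = c(0, min(t), 1e-6), upper = c(Inf, max(t), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new_fit(init[[1L]], init[[2L]], init[[3L]], sqrt(sum(
      (y - evaluate_model(list(A = init[[1L]], t0 = init[[2L]], tau = init[[3L]]),
                          t, model_kind))^2)), FALSE))
  p <- fit$par
  dev_tol <- 1e-6 * max(sum(y^2), .Machine$double.eps)
  if (model_kind == "exponential" && fit$deviance <= dev_tol) {
    # degenerate exact fit: canonicalize t0 to the first positive sample
    fp <- which(y > 0)[1L]
    refit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = y[fp], tau = p[[3L]]),
        fn = function(q) y - evaluate_model(list(A = q[1L], t0 = t[fp], tau = q[2L]),
                                            t, model_kind),
        lower = c(0, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(refit) && refit$deviance <= 1e-14 * max(sum(y^2), .Machine$double.eps))
      return(new_fit(refit$par[[1L]], t[fp], refit$par[[2L]],
                     sqrt(refit$deviance), TRUE))
  }
  # polish: with t0 held at its fitted value the problem is smooth in
  # (A, tau), so a short refit tightens them past the kinked 3-parameter
  # geometry near the Heaviside gate
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = p[[1L]], tau = p[[3L]]),
      fn = function(q) y - evaluate_model(list(A = q[1L], t0 = p[[2L]], tau = q[2L]),
                                          t, model_kind),
      lower = c(0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$deviance < fit$deviance)
    return(new_fit(polish$par[[1L]], p[[2L]], polish$par[[2L]],
                   sqrt(polish$deviance), fit$info %in% 1:4))
  new_fit(p[[1L]], p[[2L]], p[[3L]], sqrt(fit$deviance), fit$info %in% 1:4)
}

#' @export
coef.wave_model_fit <- function(object, ...) {
  c(A = object$A, t0 = object$t0, tau = object$tau)
}

#' @export
predict.wave_model_fit <- function(object, t, ...) evaluate_model(object, t)

#' @export
print.wave_model_fit <- function(x, ...) {
  cat(sprintf("<wave_model_fit:%s> A = %.5g, t0 = %.5g s, tau = %.5g s (|r| %.3g%s)\n",
              x$model_kind, x$A, x$t0, x$tau, x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit the decay model at every radial distance
#'
#' Applies [fit_decay_model()] to each radial bin's full ring-averaged time
#' series, optionally restricted to converged fits downstream.
#'
#' @param map a [ring_profile()] result.
#' @param model_kind `"exponential"` or `"quadratic"`.
#' @return a data frame with one row per valid radial bin: `r`, `A`, `t0`,
#'   `tau`, `residual_norm`, `converged`.
#' @export
fit_radial_models <- function(map, model_kind = c("exponential", "quadratic")) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(map, "radial_time_map"))
  t <- (seq_len(nrow(map$values)) - 1L) * map$frame_period
  rows <- lapply(seq_len(ncol(map$values)), function(j) {
    y <- map$values[, j]
    if (any(!is.finite(y))) return(NULL)
    fit <- tryCatch(fit_decay_model(t, pmax(y, 0), model_kind),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(r = j - 1L, A = fit$A, t0 = fit$t0, tau = fit$tau,
               residual_norm = fit$residual_norm, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(r = numeric(0), A = numeric(0),
                                      t0 = numeric(0), tau = numeric(0),
                                      residual_norm = numeric(0),
                                      converged = logical(0))
  out
}

#' Mean propagation velocity from per-radius activation times
#'
#' Regresses the fitted activation time `t0` on radial distance (robustly);
#' the inverse slope is another estimate of the mean wave velocity.
#' Non-converged per-radius fits are excluded first.
#'
#' @param radial_fits a data frame from [fit_radial_models()], or a list of
#'   `(r, wave_model_fit)` pairs.
#' @param pixel_size um/px for the physical velocity.
#' @inheritParams velocity_fit
#' @return a `robust_lm` (mode `"activation_time"`) with `velocity_px_s`
#'   and `velocity_um_s`.
#' @export
activation_velocity <- function(radial_fits, pixel_size = 1.025,
                                clip_sigma = 2, max_iter = 5L) {
  if (!is.data.frame(radial_fits)) {
    radial_fits <- do.call(rbind, lapply(radial_fits, function(p)
      data.frame(r = p[[1L]], t0 = p[[2L]]$t0, converged = p[[2L]]$converged)))
  }
  fits <- radial_fits[radial_fits$converged, , drop = FALSE]
  if (nrow(fits) < 3L) stopf("fewer than 3 converged radial fits")
  fit <- robust_linear_fit(fits$r, fits$t0, clip_sigma = clip_sigma,
                           max_iter = max_iter, mode = "activation_time")
  if (fit$slope > 0) {
    fit$velocity_px_s <- 1 / fit$slope
    fit$velocity_um_s <- pixel_size / fit$slope
  } else {
    fit$velocity_px_s <- NA_real_
    fit$velocity_um_s <- NA_real_
    fit$nonphysical <- TRUE
  }
  fit
}
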