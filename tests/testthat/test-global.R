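test_that("a single symmetric blob localizes to its center", {
  img <- blob_image(c(240, 320), matrix(c(120, 200), 1), sigma = 8)
  src <- find_source(img)
  expect_lte(max(abs(src - c(120, 200))), 1)
})

test_that("the iterative center of mass homes in on the dominant structure", {
  img <- blob_image(c(460, 460), rbind(c(60, 60), c(400, 400)),
                    sigma = c(14), amps = c(1, 0.35))
  src <- find_source(img)
  expect_lt(sqrt(sum((src - c(60, 60))^2)), 30)
  expect_gt(sqrt(sum((src - c(400, 400))^2)), 100)
})

test_that("an empty thresholded image raises the no-source error", {
  expect_error(find_source(matrix(c(0.0, 0.01), 32, 32)), "no source")
})

test_that("ring profiles average constants, steps, and conserve the disc sum", {
  stack <- array(0.7, c(41, 41, 3))
  map <- ring_profile(stack, source = c(21, 21), max_radius = 15)
  expect_true(all(abs(map$values - 0.7) < 1e-12))
  # a radial step function is reproduced exactly
  d <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`))
  g <- function(r) 1 / (1 + r)
  img <- matrix(g(floor(d)), 41, 41)
  stack2 <- array(img, c(41, 41, 2))
  map2 <- ring_profile(stack2, c(21, 21), 15)
  expect_equal(map2$values[1, ], g(0:14), tolerance = 1e-12)
  # partition: ring counts sum to the disc pixel count; weighted sums match
  expect_identical(sum(map2$counts), sum(d < 15))
  expect_equal(sum(map2$values[1, ] * map2$counts), sum(img[d < 15]),
               tolerance = 1e-9)
})

test_that("out-of-bounds radii are clipped with a warning", {
  stack <- array(1, c(21, 21, 2))
  expect_warning(map <- ring_profile(stack, c(11, 11), 50), "clipped")
  expect_lte(ncol(map$values), 11)
})

test_that("robust regression matches OLS limits and rejects gross outliers", {
  x <- seq_len(20)
  y <- 2 * x + 1
  f <- robust_linear_fit(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # one gross outlier: rejected, slope equals inlier OLS
  y2 <- c(y, 80)
  x2 <- c(x, 21)
  f2 <- robust_linear_fit(x2, y2)
  inlier <- lm(y ~ x)
  expect_equal(f2$slope, coef(inlier)[[2]], tolerance = 1e-6)
  expect_equal(f2$n_rejected, 1)
  # infinite clip_sigma reduces to plain OLS on everything
  f3 <- robust_linear_fit(x2, y2, clip_sigma = Inf)
  all_fit <- lm(y2 ~ x2)
  expect_equal(f3$slope, coef(all_fit)[[2]], tolerance = 1e-12)
  expect_equal(f3$n_rejected, 0)
  expect_error(robust_linear_fit(1:2, 1:2), "at least 3")
  expect_error(robust_linear_fit(rep(1, 5), 1:5), "degenerate")
})

test_that("velocity fits read a constructed linear front", {
  v <- 5
  nr <- 40
  times <- seq(0, 30, by = 1)
  values <- sapply(0:(nr - 1), function(r)
    evaluate_model(list(A = 0.5, t0 = r / v, tau = 15), times, "exponential"))
  map <- structure(list(values = values, counts = rep(10, nr),
                        source = c(1, 1), frame_period = 1, pixel_size = 1.025),
                   class = "radial_time_map")
  fit <- velocity_fit(map, "max_intensity")
  expect_equal(fit$velocity_px_s, v, tolerance = 0.05)
  expect_equal(fit$velocity_um_s, fit$velocity_px_s * 1.025, tolerance = 1e-9)
  fitg <- velocity_fit(map, "max_gradient")
  expect_equal(fitg$velocity_px_s, v, tolerance = 0.05)
  # a reversed front gives a non-physical negative slope
  map$values <- values[, nr:1]
  rev_fit <- velocity_fit(map, "max_intensity")
  expect_true(is.na(rev_fit$velocity_px_s))
  expect_true(rev_fit$nonphysical)
})

test_that("amplitude decay extrapolates the maximum propagation radius", {
  nr <- 60
  peak <- pmax(1 - (0:(nr - 1)) / 100, 0)
  values <- rbind(peak, peak / 2)
  map <- structure(list(values = values, counts = rep(5, nr), source = c(1, 1),
                        frame_period = 1, pixel_size = 1.025),
                   class = "radial_time_map")
  fit <- amplitude_decay_fit(map, r_min = 10)
  expect_equal(fit$slope, -0.01, tolerance = 1e-9)
  expect_equal(fit$zero_crossing_radius, 100, tolerance = 1e-6)
  # constant maxima: slope 0, undefined crossing
  map$values <- matrix(0.5, 2, nr)
  flat <- amplitude_decay_fit(map, r_min = 10)
  expect_true(is.na(flat$zero_crossing_radius))
  expect_true(flat$crossing_undefined)
})

test_that("decay models satisfy their closed forms", {
  p <- list(A = 0.8, t0 = 12, tau = 25)
  expect_equal(evaluate_model(p, 12, "exponential"), 0.8)    # H(0) = 1
  expect_equal(evaluate_model(p, 12, "quadratic"), 0.8)
  expect_equal(evaluate_model(p, 11.999, "exponential"), 0)
  expect_equal(evaluate_model(p, 12 + 25, "exponential"), 0.8 / exp(1))
  expect_equal(evaluate_model(p, 12 + 25, "quadratic"), 0.8 / 2)
  expect_error(evaluate_model(list(A = 1, t0 = 0, tau = 0), 1), "tau")
})

test_that("model fitting recovers exact series and flags degenerate input", {
  t <- seq(0, 60, by = 1)
  for (kind in c("exponential", "quadratic")) {
    y <- evaluate_model(list(A = 0.5, t0 = 10, tau = 20), t, kind)
    f <- fit_decay_model(t, y, kind)
    expect_true(f$converged)
    expect_equal(coef(f), c(A = 0.5, t0 = 10, tau = 20), tolerance = 1e-4)
  }
  zero <- fit_decay_model(t, rep(0, length(t)), "exponential")
  expect_equal(zero$A, 0)
  expect_false(zero$converged)
  expect_error(fit_decay_model(1:5, 1:5), "6 time points")
  expect_error(fit_decay_model(t, -abs(sin(t))), "non-negative")
})

test_that("model fitting is scale-equivariant", {
  t <- seq(0, 50, by = 0.5)
  y <- evaluate_model(list(A = 0.4, t0 = 8, tau = 12), t, "exponential")
  f1 <- fit_decay_model(t, y, "exponential")
  f2 <- fit_decay_model(t, y * 37, "exponential")
  expect_equal(f2$A / 37, f1$A, tolerance = 1e-6)
  expect_equal(f2$t0, f1$t0, tolerance = 1e-6)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
})

test_that("the matched model always fits at least as well as the mismatched one", {
  t <- seq(0, 60, by = 1)
  yq <- evaluate_model(list(A = 0.5, t0 = 10, tau = 20), t, "quadratic")
  fq <- fit_decay_model(t, yq, "quadratic")
  fe <- fit_decay_model(t, yq, "exponential")
  expect_equal(fq$tau, 20, tolerance = 1e-3)
  expect_gt(fe$residual_norm, fq$residual_norm)
})

test_that("activation times regress to the propagation velocity", {
  fits <- data.frame(r = 0:30, t0 = (0:30) / 5.1, converged = TRUE)
  v <- activation_velocity(fits)
  expect_equal(v$velocity_px_s, 5.1, tolerance = 1e-9)
  expect_equal(v$velocity_um_s, 5.1 * 1.025, tolerance = 1e-9)
  # non-converged fits are excluded; too few survivors is an error
  fits$converged[3:31] <- FALSE
  expect_error(activation_velocity(fits), "3 converged")
})

test_that("per-radius fits on an exact model map recover all parameters", {
  period <- 0.2
  v <- 5
  times <- seq(0, 40, by = period)
  nr <- 30
  values <- sapply(0:(nr - 1), function(r)
    evaluate_model(list(A = 0.5, t0 = r / v, tau = 20), times, "exponential"))
  map <- structure(list(values = values, counts = rep(8, nr), source = c(1, 1),
                        frame_period = period, pixel_size = 1.025),
                   class = "radial_time_map")
  rad <- fit_radial_models(map)
  expect_equal(nrow(rad), nr)
  expect_true(all(rad$converged))
  expect_lt(max(abs(rad$A - 0.5) / 0.5), 1e-6)
  expect_lt(max(abs(rad$tau - 20) / 20), 1e-6)
  expect_lt(max(abs(rad$t0 - rad$r / v)), 1e-6)
  av <- activation_velocity(rad)
  expect_equal(av$velocity_px_s, v, tolerance = 1e-6)
})
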