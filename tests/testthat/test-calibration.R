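make_ratio_seq <- function(frames, frame_period = 1, stimulus_frame = 5) {
  frame_sequence(frames, "ratio", frame_period = frame_period,
                 stimulus_frame = stimulus_frame)
}

test_that("ratio computation is exact, guarded, and drops odd trailing frames", {
  fr <- array(0, c(4, 4, 4))
  fr[, , c(1, 3)] <- 0.5
  fr[, , c(2, 4)] <- 0.25
  s <- frame_sequence(fr, c("340", "380"), 1, 2)
  r <- compute_ratio(s)
  expect_equal(dim(r$frames)[3], 2)
  expect_equal(max(abs(r$frames - 2)), 0, tolerance = 1e-4)
  # zero denominator stays finite and bounded by the guard
  fr2 <- fr
  fr2[1, 1, 2] <- 0
  s2 <- frame_sequence(fr2, c("340", "380"), 1, 2)
  r2 <- compute_ratio(s2, eps = 1e-6)
  expect_true(is.finite(r2$frames[1, 1, 1]))
  expect_lte(r2$frames[1, 1, 1], 0.5 / 1e-6)
  # odd trailing frame
  s3 <- frame_sequence(fr[, , 1:3], c("340", "380", "340"), 1, 1)
  expect_warning(r3 <- compute_ratio(s3), "odd trailing")
  expect_equal(dim(r3$frames)[3], 1)
})

test_that("marker-decay fit recovers an exact exponential flux", {
  t <- 0:9
  flux_true <- 10 * exp(-t / 50)
  fr <- array(rep(flux_true / 16, each = 16), c(4, 4, 10))
  fit <- fit_marker_decay(make_ratio_seq(fr, stimulus_frame = 11))
  expect_equal(fit$amplitude, 10, tolerance = 1e-6)
  expect_equal(fit$efold_time, 50, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-6)
  expect_identical(fit$fitted_range, 1:10)
})

test_that("constant flux yields the identity correction", {
  fr <- array(0.5, c(4, 4, 8))
  fit <- fit_marker_decay(make_ratio_seq(fr, stimulus_frame = 7))
  expect_equal(fit$amplitude, 0)
  factors <- predict(fit, 0) / predict(fit, 0:7)
  expect_equal(max(abs(factors - 1)), 0, tolerance = 1e-6)
  corrected <- correct_marker_decay(make_ratio_seq(fr, stimulus_frame = 7), fit)
  expect_equal(corrected$frames, fr, tolerance = 1e-12)
})

test_that("decay correction flattens its own fitted exponential", {
  t <- 0:19
  flux_true <- 8 * exp(-t / 30) + 2
  fr <- array(rep(flux_true / 16, each = 16), c(4, 4, 20))
  s <- make_ratio_seq(fr, stimulus_frame = 15)
  fit <- fit_marker_decay(s)
  corrected <- correct_marker_decay(s, fit)
  flux_after <- apply(corrected$frames, 3, sum)
  expect_lt(diff(range(flux_after)) / mean(flux_after), 1e-6)
})

test_that("decay fitting demands enough basal frames and positive flux", {
  fr <- array(0.5, c(4, 4, 6))
  expect_error(fit_marker_decay(make_ratio_seq(fr, stimulus_frame = 3)),
               "at least 4")
})

test_that("channel-specific bleaching is removed from generated data", {
  tr <- small_truth(decay_340 = 300, decay_380 = 150)
  ex <- generate_experiment(tr, n_frames = 40, frame_period = 1, seed = 5)
  ratio <- compute_ratio(ex$seq)
  pre <- 1:(tr$stimulus_frame - 1)
  flux_before <- apply(ratio$frames[, , pre], 3, sum)
  slope_before <- coef(lm(flux_before ~ pre))[[2]]
  fit <- fit_marker_decay(ratio)
  corrected <- correct_marker_decay(ratio, fit)
  flux_after <- apply(corrected$frames[, , pre], 3, sum)
  slope_after <- coef(lm(flux_after ~ pre))[[2]]
  expect_lt(abs(slope_after), 0.05 * abs(slope_before))
})

test_that("basal estimation sigma-rejects outliers and matches its oracle limits", {
  # identical frames: basal equals the frame exactly
  fr <- array(rep(matrix(runif(16), 4, 4), 5), c(4, 4, 5))
  s <- make_ratio_seq(fr, stimulus_frame = 6)
  expect_equal(estimate_basal(s), fr[, , 1])
  # a gross outlier among constant values is discarded
  series <- c(1, 1, 1, 1, 100)
  fr2 <- array(rep(series, each = 16), c(4, 4, 5))
  basal <- estimate_basal(make_ratio_seq(fr2, stimulus_frame = 6), sigma = 2)
  expect_equal(basal[2, 3], 1)
  # infinite sigma reduces to the plain mean
  set.seed(31)
  fr3 <- array(runif(4 * 4 * 7), c(4, 4, 7))
  expect_equal(estimate_basal(make_ratio_seq(fr3, stimulus_frame = 8),
                              sigma = Inf),
               apply(fr3, c(1, 2), mean))
  # single basal frame: returned as-is with a warning
  expect_warning(b1 <- estimate_basal(make_ratio_seq(fr3, stimulus_frame = 2)),
                 "single basal")
  expect_equal(b1, fr3[, , 1])
})

test_that("basal estimate converges statistically on noisy frames", {
  set.seed(32)
  n <- 40
  truth <- matrix(runif(20 * 20, 0.8, 1.2), 20, 20)
  fr <- array(rep(truth, n), c(20, 20, n)) +
    array(rnorm(20 * 20 * n, sd = 0.05), c(20, 20, n))
  basal <- estimate_basal(make_ratio_seq(fr, stimulus_frame = n + 1))
  frac_ok <- mean(abs(basal - truth) <= 3 * 0.05 / sqrt(n))
  expect_gte(frac_ok, 0.99)
})

test_that("wave extraction truncates, filters, and reports exact statistics", {
  basal <- matrix(1, 4, 4)
  fr <- array(1, c(4, 4, 3))
  s <- make_ratio_seq(fr, stimulus_frame = 2)
  w <- extract_wave(s, basal, median_kernel = 1)
  expect_true(all(w$wave == 0))
  expect_true(all(w$stats$maximum == 0))
  # values below basal truncate to zero
  fr2 <- fr; fr2[2, 2, 1] <- 0.8
  w2 <- extract_wave(make_ratio_seq(fr2, stimulus_frame = 2), basal, 1)
  expect_equal(w2$wave[2, 2, 1], 0)
  # per-pixel series (0, 0.3, 0.1) at 1 s cadence
  fr3 <- array(1, c(4, 4, 3))
  fr3[3, 3, ] <- 1 + c(0, 0.3, 0.1)
  w3 <- extract_wave(make_ratio_seq(fr3, stimulus_frame = 2), basal, 1)
  expect_equal(w3$stats$maximum[3, 3], 0.3)
  expect_equal(w3$stats$t_max[3, 3], 1)
  expect_equal(w3$stats$mean[3, 3], mean(c(0, 0.3, 0.1)))
  expect_equal(w3$stats$sd[3, 3], sd(c(0, 0.3, 0.1)))
  expect_error(extract_wave(s, basal, median_kernel = 4), "kernel")
  expect_error(extract_wave(s, basal, median_kernel = 7), "kernel")
})

test_that("wave extraction is invariant to a common offset of ratio and basal", {
  set.seed(33)
  fr <- array(runif(6 * 6 * 5, 0.9, 1.4), c(6, 6, 5))
  basal <- matrix(1, 6, 6)
  w1 <- extract_wave(make_ratio_seq(fr, stimulus_frame = 3), basal, 3)
  w2 <- extract_wave(make_ratio_seq(fr + 0.7, stimulus_frame = 3), basal + 0.7, 3)
  expect_equal(w1$wave, w2$wave, tolerance = 1e-6)
  expect_true(all(w1$wave >= 0))
})

test_that("time of maximum grows with distance from the source on clean data", {
  tr <- small_truth()
  ex <- generate_experiment(tr, n_frames = 30, frame_period = 1, seed = 6)
  w <- calibrate(ex$seq, register = FALSE, median_kernel = 1)
  d <- sqrt(outer((1:96 - 48)^2, (1:96 - 48)^2, `+`))
  sel <- tr$footprint & d > 2
  expect_gt(cor(d[sel], w$stats$t_max[sel]), 0.98)
  # ring-averaged time of maximum is monotone non-decreasing with radius
  ring_t <- vapply(2:38, function(r)
    mean(w$stats$t_max[d >= r & d < r + 1]), 0)
  expect_true(all(diff(ring_t) >= -1e-9))
})
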