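test_that("a stream identical to its basal level yields a zero wave", {
  fr <- array(rep(matrix(0.35, 8, 8), 12), c(8, 8, 12))
  s <- frame_sequence(fr, "380", frame_period = 0.5, stimulus_frame = 11)
  w <- extract_wave_single(s, register = FALSE, decay_correct = FALSE,
                           median_kernel = 1)
  expect_true(all(w$wave == 0))
})

test_that("a 380 nm dip of known depth appears as a positive wave of that depth", {
  fr <- array(0.35, c(8, 8, 14))
  fr[4, 5, 13:14] <- 0.35 - 0.08
  s <- frame_sequence(fr, "380", frame_period = 0.5, stimulus_frame = 12)
  w <- extract_wave_single(s, register = FALSE, decay_correct = FALSE,
                           median_kernel = 1)
  expect_equal(w$wave[4, 5, 13], 0.08, tolerance = 1e-12)
  expect_true(all(w$wave >= 0))
})

test_that("max-intensity velocity is refused for single-filter data", {
  tr <- small_truth()
  sf <- generate_single_filter(tr, n_frames = 30, frame_period = 1, seed = 3)
  w <- extract_wave_single(sf, register = FALSE)
  expect_error(single_filter_velocity(w, c(48, 48), 30, mode = "max_intensity"),
               "not supported")
})

test_that("single- and two-filter gradient velocities agree on paired truth", {
  tr <- small_truth(velocity = 5, footprint_radius = 35)
  fp_two <- 1
  fp_one <- 1 / 2.8
  ex <- generate_experiment(tr, n_frames = 35, frame_period = fp_two, seed = 13)
  w2 <- calibrate(ex$seq, register = FALSE)
  v2 <- velocity_fit(ring_profile(w2, c(48, 48), 35), "max_gradient")
  tr1 <- small_truth(velocity = 5, footprint_radius = 35,
                     stimulus_frame = ceiling(11 * fp_two / fp_one) + 1)
  sf <- generate_single_filter(tr1, n_frames = 100, frame_period = fp_one,
                               seed = 13)
  w1 <- extract_wave_single(sf, register = FALSE)
  v1 <- single_filter_velocity(w1, c(48, 48), 35)
  expect_lt(abs(v1$velocity_px_s - v2$velocity_px_s) / v2$velocity_px_s, 0.1)
})

test_that("faster sampling reduces the quantization error of the front times", {
  tr <- small_truth(velocity = 5, footprint_radius = 35,
                    stimulus_frame = 12)
  slow <- generate_single_filter(tr, n_frames = 40, frame_period = 1, seed = 5)
  trf <- small_truth(velocity = 5, footprint_radius = 35, stimulus_frame = 23)
  fast <- generate_single_filter(trf, n_frames = 80, frame_period = 0.5, seed = 5)
  vslow <- single_filter_velocity(extract_wave_single(slow, register = FALSE),
                                  c(48, 48), 35)
  vfast <- single_filter_velocity(extract_wave_single(fast, register = FALSE),
                                  c(48, 48), 35)
  # the per-bin front-time quantization bound halves with the period
  err_slow <- max(abs(vslow$t_feature[10:30] - (9:29) / 5 - 11))
  err_fast <- max(abs(vfast$t_feature[10:30] - (9:29) / 5 - 11))
  expect_lte(err_fast, err_slow)
  expect_lt(abs(vfast$velocity_px_s - 5) / 5, 0.05)
})
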