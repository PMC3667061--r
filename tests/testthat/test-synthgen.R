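test_that("noiseless generator reproduces the exact ratio at and before activation", {
  tr <- small_truth()
  ex <- generate_experiment(tr, n_frames = 30, frame_period = 1, seed = 1)
  seq <- ex$seq
  # ratio at the source pixel at its activation instant equals basal + A
  t_stim <- (tr$stimulus_frame - 1) * 1
  i_act <- tr$stimulus_frame            # t0(source) = 0 => first post-stimulus frame
  r340 <- seq$frames[48, 48, 2 * i_act - 1]
  r380 <- seq$frames[48, 48, 2 * i_act]
  expect_equal(r340 / r380, tr$basal_ratio + 0.5, tolerance = 1e-12)
  # any pixel before its activation time shows the pure basal ratio
  px <- c(48, 70)                       # 22 px out: t0 = 22/5 = 4.4 s
  i_pre <- tr$stimulus_frame + 2        # 2 s after stimulus < 4.4 s
  expect_equal(seq$frames[px[1], px[2], 2 * i_pre - 1] /
                 seq$frames[px[1], px[2], 2 * i_pre],
               tr$basal_ratio, tolerance = 1e-12)
  expect_identical(seq$channels[1:4], c("340", "380", "340", "380"))
})

test_that("generation is bit-identical for a fixed seed and differs across seeds", {
  tr <- small_truth(noise_sigma = 0.01)
  a <- generate_experiment(tr, n_frames = 15, frame_period = 1, seed = 7)
  b <- generate_experiment(tr, n_frames = 15, frame_period = 1, seed = 7)
  c <- generate_experiment(tr, n_frames = 15, frame_period = 1, seed = 8)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_false(identical(a$seq$frames, c$seq$frames))
})

test_that("ground-truth maps satisfy the wave-geometry invariants", {
  tr <- small_truth(velocity = 3)
  expect_true(all(dim(tr$amplitude_map) == tr$shape))
  expect_true(all(dim(tr$tau_map) == tr$shape))
  d <- sqrt(outer((1:96 - 48)^2, (1:96 - 48)^2, `+`))
  inside <- tr$footprint
  expect_equal(tr$t0_map[inside], d[inside] / 3, tolerance = 1e-12)
  expect_true(all(tr$tau_map > 0))
  expect_true(all(tr$amplitude_map[!inside] == 0))
})

test_that("invalid physical parameters are rejected", {
  expect_error(small_truth(velocity = -1), "velocity")
  expect_error(small_truth(tau = 0), "tau")
  expect_error(ground_truth(c(96, 96), c(48, 48), 5, stimulus_frame = 5),
               "pre-stimulus")
  tr <- small_truth()
  expect_error(generate_experiment(tr, n_frames = 30, frame_period = 0),
               "frame_period")
  expect_error(generate_experiment(tr, n_frames = 10, frame_period = 1),
               "n_frames")
})

test_that("single-filter stream dips below basal inside the activated footprint", {
  tr <- small_truth()
  sf <- generate_single_filter(tr, n_frames = 40, frame_period = 0.5, seed = 1)
  expect_true(all(sf$channels == "380"))
  basal_level <- sf$frames[48, 60, 1]          # pre-stimulus, 12 px from source
  # shortly after that pixel activates (t0 = 12/5 = 2.4 s after stimulus)
  i_post <- ceiling(((tr$stimulus_frame - 1) * 0.5 + 2.4) / 0.5) + 2
  expect_lt(sf$frames[48, 60, i_post], basal_level)
})

test_that("the faster single-filter rate yields proportionally more frames", {
  # equal wall time at 2.8 vs 0.8 frames per second: 3.5x the frames
  wall <- 60
  expect_equal((wall * 2.8) / (wall * 0.8), 3.5)
  tr <- small_truth()
  fast <- generate_single_filter(tr, n_frames = round(wall * 2.8),
                                 frame_period = 1 / 2.8, seed = 1)
  slow <- generate_single_filter(tr, n_frames = round(wall * 0.8),
                                 frame_period = 1 / 0.8, seed = 1)
  expect_equal(dim(fast$frames)[3] / dim(slow$frames)[3], 3.5, tolerance = 0.02)
})

test_that("ground truth round-trips through the plain-text + FITS sidecar", {
  tr <- small_truth()
  dir <- withr::local_tempdir()
  write_ground_truth(tr, dir)
  side <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(side$velocity, 5)
  amp <- read_fits(file.path(dir, "truth_amplitude.fits"))
  expect_equal(dim(amp), c(96, 96))
  expect_equal(max(abs(amp - tr$amplitude_map)), 0, tolerance = 1e-6)
})
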