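# shared fixtures, built in code

# a compact standard experiment: 96 x 96 px, source centred, wave of 40 px
small_truth <- function(velocity = 5, amplitude = 0.5, tau = 20,
                        stimulus_frame = 12, footprint_radius = 40, ...) {
  ground_truth(shape = c(96, 96), source = c(48, 48), velocity = velocity,
               stimulus_frame = stimulus_frame, amplitude = amplitude,
               tau = tau, footprint_radius = footprint_radius, ...)
}

# textured frame with a few Gaussian blobs, for registration / source tests
blob_image <- function(shape, centers, sigma = 6, amps = 1, texture = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amps <- rep_len(amps, nrow(centers))
  img <- matrix(0, shape[1L], shape[2L])
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(shape[1L]) - centers[k, 1L])^2,
                (seq_len(shape[2L]) - centers[k, 2L])^2, `+`)
    img <- img + amps[k] * exp(-d2 / (2 * sigma^2))
  }
  if (texture > 0)
    img <- img * matrix(runif(prod(shape), 1 - texture, 1 + texture),
                        shape[1L], shape[2L])
  img
}

# per-pixel stack built directly from decay-model parameter maps
model_stack <- function(A_map, t0_map, tau_map, times,
                        model_kind = "exponential") {
  d <- dim(A_map)
  stack <- array(0, c(d, length(times)))
  for (i in seq_along(times)) {
    dt <- times[i] - t0_map
    gate <- (dt >= 0) & (A_map > 0)
    fr <- matrix(0, d[1L], d[2L])
    fr[gate] <- if (model_kind == "exponential")
      A_map[gate] * exp(-dt[gate] / tau_map[gate])
    else A_map[gate] * tau_map[gate]^2 / (tau_map[gate]^2 + dt[gate]^2)
    stack[, , i] <- fr
  }
  stack
}

# brute-force sigma-clipped mean of one vector (independent oracle)
clip_mean_oracle <- function(x, sigma) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0 || !is.finite(sigma)) return(m)
  keep <- abs(x - m) < sigma * s
  if (!any(keep)) m else mean(x[keep])
}
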