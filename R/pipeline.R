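# End-to-end orchestration with a serializable run configuration.

#' Default pipeline configuration
#'
#' All stage parameters in one plain list, serializable to YAML with
#' [write_config()] so a saved configuration re-runs bit-identically on the
#' same input.
#'
#' @param input directory (or file pattern) of the raw TIFF sequence.
#' @param out_dir output directory; `NULL` disables file output.
#' @param ... overrides for any default entry.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(input = NULL, out_dir = NULL, ...) {
  cfg <- list(
    input = input, out_dir = out_dir,
    channel_rule = "filename", frame_period = 1, stimulus_frame = 11L,
    pixel_size = 1.025,
    keep_scale = 1L, register = TRUE, decay_correct = TRUE,
    sigma = 2, median_kernel = 3L, eps = 1e-6,
    masking = TRUE, threshold = NULL, morph_close = 7L, morph_open = 7L,
    source = NULL, max_radius = NULL, r_min = 10,
    model_kind = "exponential", local = FALSE,
    clip_sigma = 2, seed = 1L, verbose = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes calibration, optional masking, global analysis (source
#' localization, ring reduction, velocity and decay-model fits) and
#' optional local analysis, in order, from a single configuration.  When
#' `config$out_dir` is set, the wave stack, statistics, mask, radial-time
#' map and parameter maps are written as 32-bit FITS together with the
#' per-radius fit table (CSV), the summary and the exact configuration
#' used.
#'
#' @param config a [run_config()] (or a YAML path understood by
#'   [read_config()]).
#' @param seq optionally, an in-memory [frame_sequence()] to analyze
#'   instead of reading `config$input`.
#' @return an object of class `cawave_run`: the summary (velocities in
#'   px/s and um/s from the three estimators, zero-crossing radius, mean
#'   decay rate), the per-radius fit table, and the intermediate stage
#'   objects.
#' @export
run_pipeline <- function(config, seq = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline failed in stage '%s': %s", name, conditionMessage(e)))
  }
  if (is.null(seq)) {
    if (is.null(config$input)) stopf("config$input is required when no sequence is given")
    say("reading sequence from %s", config$input)
    seq <- stage("read", read_sequence(config$input,
                                       channel_rule = config$channel_rule,
                                       frame_period = config$frame_period,
                                       stimulus_frame = config$stimulus_frame,
                                       pixel_size = config$pixel_size))
  }
  say("calibrating (%d frames)", dim(seq$frames)[3L])
  wave <- stage("calibrate",
                calibrate(seq, keep_scale = config$keep_scale,
                          sigma = config$sigma,
                          median_kernel = config$median_kernel,
                          register = config$register,
                          decay_correct = config$decay_correct,
                          eps = config$eps))
  source <- config$source
  if (is.null(source)) {
    say("localizing the propagation source")
    source <- stage("source",
                    find_source(wave$wave[, , min(wave$stimulus_frame + 1L,
                                                  dim(wave$wave)[3L])]))
  }
  mask <- NULL
  if (isTRUE(config$masking)) {
    say("building the signal mask")
    mask <- stage("mask",
                  build_mask(wave, threshold = config$threshold,
                             morph_ops = list(list("close", config$morph_close),
                                              list("open", config$morph_open)),
                             max_radius = config$max_radius, source = source))
    if (mask$empty) {
      warnf("empty signal mask: continuing without masking")
      mask <- NULL
    }
  }
  d <- dim(wave$wave)
  max_radius <- config$max_radius %||%
    floor(min(source[1L] - 1, d[1L] - source[1L],
              source[2L] - 1, d[2L] - source[2L]))
  say("ring reduction to radius %d px about (%d, %d)", max_radius,
      source[1L], source[2L])
  map <- stage("global", ring_profile(wave, source = source,
                                      max_radius = max_radius, mask = mask))
  v_grad <- stage("global", velocity_fit(map, "max_gradient",
                                         clip_sigma = config$clip_sigma))
  v_int <- stage("global", velocity_fit(map, "max_intensity",
                                        clip_sigma = config$clip_sigma))
  amp <- tryCatch(amplitude_decay_fit(map, r_min = config$r_min,
                                      clip_sigma = config$clip_sigma),
                  error = function(e) NULL)
  say("fitting %s decay models per radius", config$model_kind)
  radial <- stage("global", fit_radial_models(map, config$model_kind))
  v_act <- tryCatch(activation_velocity(radial, pixel_size = map$pixel_size,
                                        clip_sigma = config$clip_sigma),
                    error = function(e) NULL)
  local_maps <- NULL
  if (isTRUE(config$local)) {
    say("local per-pixel fits")
    local_maps <- stage("local", fit_pixelwise(wave, mask = mask,
                                               model_kind = config$model_kind))
  }
  summary <- list(
    source = source,
    velocity_gradient_px_s = v_grad$velocity_px_s,
    velocity_gradient_um_s = v_grad$velocity_um_s,
    velocity_intensity_px_s = v_int$velocity_px_s,
    velocity_intensity_um_s = v_int$velocity_um_s,
    velocity_activation_px_s = if (!is.null(v_act)) v_act$velocity_px_s else NA_real_,
    velocity_activation_um_s = if (!is.null(v_act)) v_act$velocity_um_s else NA_real_,
    zero_crossing_radius_px = if (!is.null(amp)) amp$zero_crossing_radius else NA_real_,
    mean_decay_rate_s = if (nrow(radial)) mean(radial$tau[radial$converged]) else NA_real_,
    n_radial_bins = ncol(map$values),
    mask_area_px = if (!is.null(mask)) sum(mask$mask) else NA_real_
  )
  run <- structure(list(summary = summary, config = config, wave = wave,
                        mask = mask, map = map, radial_fits = radial,
                        fits = list(gradient = v_grad, intensity = v_int,
                                    amplitude = amp, activation = v_act),
                        local = local_maps),
                   class = "cawave_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# write all pipeline products of a run to disk
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- c(list(wave = run$wave$wave, basal = run$wave$basal),
              run$wave$stats,
              list(radial_time_map = {
                v <- run$map$values; v[is.na(v)] <- 0; v
              }))
  if (!is.null(run$mask)) images$mask <- run$mask$mask
  if (!is.null(run$local))
    images <- c(images, run$local[c("amplitude", "activation_time",
                                    "decay_rate", "converged", "residual")])
  write_outputs(images, out_dir)
  utils::write.csv(run$radial_fits, file.path(out_dir, "radial_fits.csv"),
                   row.names = FALSE)
  write_config(run$config, file.path(out_dir, "config_used.yaml"))
  yaml::write_yaml(lapply(run$summary, function(v)
    if (is.numeric(v)) as.numeric(v) else v), file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}

#' @export
print.cawave_run <- function(x, ...) {
  s <- x$summary
  cat("<cawave_run>\n")
  cat(sprintf("  source: (%d, %d)\n", s$source[1L], s$source[2L]))
  cat(sprintf("  wave-front velocity (max gradient) : %.4g px/s = %.4g um/s\n",
              s$velocity_gradient_px_s, s$velocity_gradient_um_s))
  cat(sprintf("  peak velocity (max intensity)      : %.4g px/s = %.4g um/s\n",
              s$velocity_intensity_px_s, s$velocity_intensity_um_s))
  cat(sprintf("  activation-time velocity (model)   : %.4g px/s = %.4g um/s\n",
              s$velocity_activation_px_s, s$velocity_activation_um_s))
  cat(sprintf("  max propagation radius (extrapol.) : %.4g px\n",
              s$zero_crossing_radius_px))
  cat(sprintf("  mean decay rate                    : %.4g s\n", s$mean_decay_rate_s))
  invisible(x)
}
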