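#' Run configuration
#'
#' @param experiment one of `"tpsf"`, `"gate_scan"`, `"budget"`,
#'   `"phantom_image"`, `"binning_study"`, `"invivo_demo"`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param n_photons photon count for Monte Carlo experiments.
#' @param ... experiment-specific overrides (e.g. `gate_delays`,
#'   `bin_pitches`, `render_pixels`, `smooth_sigma`, head-model config
#'   path `model_config`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(experiment, out_dir = "runs", seed = 1,
                       n_photons = 1e7, ...) {
  experiment <- match.arg(experiment,
                          c("tpsf", "gate_scan", "budget", "phantom_image",
                            "binning_study", "invivo_demo"))
  structure(c(list(experiment = experiment, out_dir = out_dir,
                   seed = as.integer(seed), n_photons = n_photons),
              list(...)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; unknown keys pass through as
#' experiment-specific options. Schema violations raise an error naming
#' the offending key.
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's keys (CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$experiment))
    stop(sprintf("%s: missing required key 'experiment'", path))
  bad <- !vapply(cfg, function(v) is.atomic(v) || is.list(v), TRUE)
  if (any(bad))
    stop(sprintf("%s: invalid value for key '%s'", path,
                 names(cfg)[bad][1]))
  do.call(run_config, cfg)
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run one reproduction experiment
#'
#' Executes the configured experiment with the package's building blocks,
#' writes its result files (CSV curves, float TIFF images, JSON budget
#' reports) into the output directory, and returns — and writes as
#' `summary.json` — a summary containing the main quantities the run
#' computed. Deterministic given the config's seed; the summary records
#' the config hash and every physical parameter used.
#'
#' @param config a [run_config()].
#' @return the summary, invisibly (a named list).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- make_phantom_scene()
  if (!is.null(config$model_config))
    scene$model <- read_head_config(config$model_config)
  summary <- switch(
    config$experiment,
    tpsf = .exp_tpsf(config, scene),
    gate_scan = .exp_gate_scan(config, scene),
    budget = .exp_budget(config),
    phantom_image = .exp_phantom_image(config, scene),
    binning_study = .exp_binning(config, scene),
    invivo_demo = .exp_invivo(config))
  summary <- c(list(experiment = config$experiment,
                    config = unclass(config),
                    config_hash = .config_hash(config)), summary)
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.exp_tpsf <- function(config, scene) {
  tl <- mc_simulate(scene$model_rest, scene$source, scene$detector_10mm,
                    slab = scene$slab, n_photons = config$n_photons,
                    seed = config$seed, keep_layer_paths = FALSE)
  ts <- tpsf(tl, bin_width = config$bin_width %||% 0.025)
  write_tpsf(ts, file.path(config$out_dir, "tpsf_impulse.csv"))
  sq <- convolve_pulse(ts, scene$pulse)
  write_tpsf(sq, file.path(config$out_dir, "tpsf_square11ns.csv"))
  curve <- mean_partial_path_vs_time(
    tl, breaks = config$time_breaks %||% seq(0, 3, by = 0.25))
  write_curve_csv(curve, file.path(config$out_dir, "slab_path_vs_time.csv"))
  list(detected_fraction = tl$totals$detected / tl$totals$launched,
       n_detected = tl$totals$n_detected,
       weight_balance_error = weight_balance_error(tl))
}

.exp_gate_scan <- function(config, scene) {
  tl <- mc_simulate(scene$model_rest, scene$source, scene$detector_10mm,
                    n_photons = config$n_photons, seed = config$seed,
                    keep_layer_paths = FALSE)
  delays <- config$gate_delays %||% seq(0, 2, by = 0.2)
  rr <- lapply(delays, function(d)
    gated_reflection_ratio(tl, shutter_window(d, 11), scene$pulse))
  df <- data.frame(delay_ns = delays,
                   reflection_ratio = vapply(rr, as.numeric, 0),
                   se = vapply(rr, attr, 0, "se"))
  utils::write.csv(df, file.path(config$out_dir, "gate_scan.csv"),
                   row.names = FALSE)
  r08 <- gated_reflection_ratio(tl, shutter_window(0.8, 11), scene$pulse)
  ts <- tpsf(tl, bin_width = 0.025)
  sq <- convolve_pulse(ts, scene$pulse)
  imp <- set_time_origin(ts, "pulse_off_edge", 0.01)
  gain <- superimposition_gain(gated_fraction(imp, shutter_window(0.8, 11)),
                               gated_fraction(sq, shutter_window(0.8, 11)))
  list(reflection_ratio_0p8ns = as.numeric(r08),
       reflection_ratio_se = attr(r08, "se"),
       superimposition_gain_0p8ns = gain)
}

.exp_budget <- function(config) {
  params <- reference_budget()
  rep <- noise_report(params)
  write_budget_json(rep, file.path(config$out_dir, "budget.json"))
  list(signal_energy_J = rep$exact$energy_J,
       electrons = rep$exact$signal_electrons,
       electrons_printed_chain = rep$printed$signal_electrons_rounded,
       shot_noise = rep$exact$shot_noise_electrons,
       shot_noise_printed_chain = rep$printed$shot_noise_rounded,
       solid_angle_sr = params$Omega,
       shutter_open_ms = rep$shutter_open_s * 1e3,
       sampling_density_per_cm2 = sampling_density(c(64, 44), c(320, 240)))
}

.exp_phantom_image <- function(config, scene) {
  px <- config$render_pixels %||% c(64, 44)
  sig <- config$smooth_sigma %||% 18 * px[1] / scene$view$pixels[1]
  imgs <- render_delta_od(scene$model, scene$view, scene$pulse,
                          scene$gates, n_photons = config$n_photons,
                          seed = config$seed, render_pixels = px)
  imgs <- lapply(imgs, gaussian_smooth, sigma_px = sig)
  rod_dod <- vapply(imgs, function(im) {
    cc <- pixel_centers(im)
    im$grid[which.min(abs(cc$y)), which.min(abs(cc$x))]
  }, 0)
  for (nm in names(imgs))
    write_delta_od_tiff(imgs[[nm]],
                        file.path(config$out_dir, paste0(nm, ".tiff")),
                        meta = list(gate = nm, seed = config$seed,
                                    smooth_sigma_px = sig))
  mets <- blob_metrics(imgs[[length(imgs)]])
  c(list(rod_center_dod = as.list(rod_dod),
         smooth_sigma_px = sig), mets[c("peak", "centroid_xy",
                                        "fwhm_equiv")])
}

.exp_binning <- function(config, scene) {
  px <- config$render_pixels %||% c(64, 44)
  sig <- config$smooth_sigma %||% 18 * px[1] / scene$view$pixels[1]
  img <- render_delta_od(scene$model, scene$view, scene$pulse,
                         scene$gates[[3]], n_photons = config$n_photons,
                         seed = config$seed, render_pixels = px)
  img <- gaussian_smooth(img, sig)
  base <- blob_metrics(normalize_image(img))
  pitches <- config$bin_pitches %||% c(10, 20, 30)
  out <- lapply(pitches, function(p) {
    b <- bin_resample(img, p)
    write_delta_od_tiff(b, file.path(config$out_dir,
                                     sprintf("binned_%gmm.tiff", p)),
                        meta = list(pitch_mm = p, seed = config$seed))
    m <- blob_metrics(b)
    list(pitch_mm = p, fwhm_equiv = m$fwhm_equiv,
         centroid_xy = m$centroid_xy,
         centroid_shift_mm = sqrt(sum((m$centroid_xy -
                                         base$centroid_xy)^2)))
  })
  list(unbinned_fwhm = base$fwhm_equiv,
       unbinned_centroid = base$centroid_xy, binned = out)
}

.exp_invivo <- function(config) {
  spec <- invivo_spec(seed = config$seed)
  gen <- make_invivo_stack(spec)
  res <- process_invivo(gen$late, protocol = spec$protocol)
  write_haemo_csv(res$average,
                  file.path(config$out_dir, "trial_average.csv"))
  utils::write.csv(res$spectrum,
                   file.path(config$out_dir, "power_spectrum.csv"),
                   row.names = FALSE)
  list(task_minus_rest_hbo = res$task_minus_rest,
       trials_task_positive = res$trials_task_positive,
       n_trials = spec$protocol$n_trials)
}

#' Full in-vivo processing chain
#'
#' The complete signal chain for a dual-wavelength interleaved stack:
#' background subtraction, de-interleave, per-pixel ΔOD against the
#' pre-task baseline, ROI averaging around a pixel, MBLL inversion to
#' ΔHbO·L / ΔHbR·L, anchored baseline correction, zero-phase 0.01-0.1 Hz
#' band-pass, per-trial splitting, and normalized trial averaging.
#'
#' @param stack an interleaved [frame_stack()] (with dark frames, or
#'   already background-subtracted).
#' @param protocol a [task_protocol()].
#' @param eps an [extinction_matrix()].
#' @param pixel centre of the region of interest in half-resolution
#'   (single-wavelength) row/col coordinates; default frame centre.
#' @param roi_half half-width of the square ROI averaged before
#'   inversion (default 5 pixels).
#' @param band band-pass edges in Hz (`NULL` to skip filtering).
#' @param baseline_anchors anchor times (s) for the per-trial linear
#'   baseline; `NULL` to skip.
#' @return a list: `hbo`, `hbr` (full-record ROI series), `trials`,
#'   `average` (normalized trial average), `spectrum` (power spectrum of
#'   the unaveraged ΔHbO·L), `task_minus_rest` (mean normalized task-epoch
#'   minus rest-epoch ΔHbO·L), `trials_task_positive` (count of trials
#'   with task mean above rest mean).
#' @export
process_invivo <- function(stack, protocol = task_protocol(),
                           eps = extinction_matrix(), pixel = NULL,
                           roi_half = 5, band = c(0.01, 0.1),
                           baseline_anchors = c(30, 85)) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.null(stack$dark)) stack <- subtract_background(stack)
  waves <- deinterleave(stack)
  fs <- stack$frame_rate
  base_frames <- seq_len(max(1L, round(protocol$rest_before * fs)))
  roi_series <- function(wstack) {
    d <- dim(wstack$frames)
    ctr <- pixel %||% c(round(d[1] / 2), round(d[2] / 2))
    rs <- pmax(1L, ctr[1] - roi_half):pmin(d[1], ctr[1] + roi_half)
    cs <- pmax(1L, ctr[2] - roi_half):pmin(d[2], ctr[2] + roi_half)
    roi <- apply(wstack$frames[rs, cs, , drop = FALSE], 3, mean)
    roi_stack <- frame_stack(array(roi, c(1, 1, d[3])), fs)
    as.numeric(delta_od_series(roi_stack, base_frames))
  }
  dod750 <- roi_series(waves[["750"]])
  dod855 <- roi_series(waves[["855"]])
  hb <- mbll_invert(dod750, dod855, eps)
  hbo <- hb$hbo
  hbr <- hb$hbr
  if (!is.null(band)) {
    hbo <- bandpass(hbo, band[1], band[2], fs)
    hbr <- bandpass(hbr, band[1], band[2], fs)
  }
  trials <- split_trials(hbo, hbr, fs, protocol)
  if (!is.null(baseline_anchors))
    trials <- lapply(trials, function(tr)
      haemo_series(tr$time,
                   baseline_correct(tr$hbo, fs, baseline_anchors),
                   baseline_correct(tr$hbr, fs, baseline_anchors)))
  avg <- trial_average(trials)
  on <- protocol$rest_before
  off <- on + protocol$task
  task_idx <- avg$time >= on + 5 & avg$time <= off + 5 # haemodynamic lag
  rest_idx <- avg$time < on | avg$time > off + 15
  per_trial_delta <- vapply(trials, function(tr)
    mean(tr$hbo[task_idx]) - mean(tr$hbo[rest_idx]), 0)
  list(hbo = hb$hbo, hbr = hb$hbr, trials = trials, average = avg,
       spectrum = power_spectrum(hb$hbo, fs),
       task_minus_rest = mean(avg$hbo[task_idx]) - mean(avg$hbo[rest_idx]),
       trials_task_positive = sum(per_trial_delta > 0),
       per_trial_delta = per_trial_delta)
}
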