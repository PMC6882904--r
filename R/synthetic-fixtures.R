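#' Tissue-equivalent phantom scene
#'
#' The layered head phantom used throughout: scalp and skull 10 mm
#' (mu_s' = 1.8, mu_a = 0.019 mm^-1), cerebrospinal fluid 2 mm (0.3, 0),
#' semi-infinite brain (2.1, 0.04), with a 10-mm-diameter absorption rod
#' (mu_s' = 2.1, mu_a = 0.05, i.e. delta_mua = 0.01 mm^-1 over the brain
#' background) embedded in the brain layer; a camera 150 mm from the
#' surface with a 64 x 44 mm field of view and 320 x 240 pixels; an 11-ns
#' square emission pulse; and 11-ns shutter windows opening 0, 0.4 and
#' 0.8 ns after the pulse-off reference.
#'
#' @param rod_depth depth of the rod's shallow end below the surface (mm);
#'   default 12, flush with the brain top.
#' @param rod_length rod length (mm), axis along z (the viewing axis, so
#'   the rod projects as a 10-mm circle).
#' @param rod_delta_mua absorption change inside the rod (mm^-1).
#' @return a list with `model` ([head_model()] incl. rod), `model_rest`
#'   (no rod), `view` ([camera_view()]), `source` (the MC illumination
#'   rectangle of the single-detector studies), `detector_1mm`,
#'   `detector_10mm`, `slab` (brain 0-4 mm), `pulse` ([pulse_shape()]),
#'   `gates` (list of [shutter_window()]).
#' @export
make_phantom_scene <- function(rod_depth = 12, rod_length = 30,
                               rod_delta_mua = 0.01) {
  layers <- list(
    head_layer(10, 1.8, 0.019, name = "scalp_skull"),
    head_layer(2, 0.3, 0, name = "csf"),
    head_layer(Inf, 2.1, 0.04, name = "brain"))
  rod <- inclusion_cylinder(10, c(0, 0, rod_depth + rod_length / 2),
                            axis = "z", length = rod_length,
                            delta_mua = rod_delta_mua)
  list(model = head_model(layers, rod),
       model_rest = head_model(layers),
       view = camera_view(c(64, 44), c(320, 240), 150),
       source = source_rect(64, 18),
       detector_1mm = detector_rect(1, 1),
       detector_10mm = detector_rect(10, 10),
       slab = depth_slab(3, 0, 4),
       pulse = pulse_shape(11),
       gates = list(shutter_window(0, 11), shutter_window(0.4, 11),
                    shutter_window(0.8, 11)))
}

#' Specification of a synthetic in-vivo recording
#'
#' Parameters of the dual-wavelength frame-stack generator emulating the
#' block-task protocol: a task-locked haemodynamic response (trapezoidal
#' rise/plateau/fall), a negative deoxy counterpart, a ~0.1 Hz
#' low-frequency oscillation, a 1.1 Hz cardiac component, and shot noise
#' at the photon budget's electron scale. The superficial (LFO + cardiac)
#' components appear at full amplitude in the early-gate channel and at
#' `superficial_share` of it in the late-gate channel; the task response
#' appears only in the late-gate (deep) channel.
#'
#' @param protocol a [task_protocol()] (default 30 s rest / 25 s task /
#'   30 s rest, 5 trials).
#' @param frame_rate frames per second (default 5).
#' @param pixels frame size, rows x cols (rows must be even; default
#'   24 x 24 — a cropped sensor region keeps generated stacks small while
#'   spanning many rows of each wavelength).
#' @param hrf_amp task-response amplitude in ΔHbO·L units (mM·mm).
#' @param hrf_tau onset/offset ramp time constant (s).
#' @param hbr_ratio ΔHbR·L / ΔHbO·L of the task response (negative).
#' @param lfo amplitude (mM·mm) and frequency (Hz) of the low-frequency
#'   oscillation, as `list(amp=, freq=)`.
#' @param cardiac amplitude and frequency of the cardiac component.
#' @param superficial_share fraction of the superficial components
#'   reaching the late-gate channel.
#' @param budget a [budget_params()]; its electron count sets the
#'   per-pixel per-frame shot-noise scale.
#' @param dark_mean mean dark/background electron count per pixel.
#' @param seed integer seed.
#' @return an object of class `invivo_spec`.
#' @export
invivo_spec <- function(protocol = task_protocol(), frame_rate = 5,
                        pixels = c(24, 24), hrf_amp = 0.2, hrf_tau = 5,
                        hbr_ratio = -0.3,
                        lfo = list(amp = 0.1, freq = 0.1),
                        cardiac = list(amp = 0.02, freq = 1.1),
                        superficial_share = 0.5,
                        budget = reference_budget(), dark_mean = 10,
                        seed = 1) {
  stopifnot(inherits(protocol, "task_protocol"), frame_rate > 0,
            pixels[1] %% 2 == 0, hrf_amp >= 0, hrf_tau > 0,
            hbr_ratio <= 0, lfo$amp >= 0, cardiac$amp >= 0,
            superficial_share >= 0, superficial_share <= 1)
  if (lfo$freq >= frame_rate / 2)
    stop("LFO frequency must be below the frame-rate Nyquist")
  structure(list(protocol = protocol, frame_rate = frame_rate,
                 pixels = as.integer(pixels), hrf_amp = hrf_amp,
                 hrf_tau = hrf_tau, hbr_ratio = hbr_ratio, lfo = lfo,
                 cardiac = cardiac, superficial_share = superficial_share,
                 budget = budget, dark_mean = dark_mean, seed = seed),
            class = "invivo_spec")
}

#' Reference photon budget of the imaging system
#'
#' The worked signal-chain parameters: 4.8e-10 J per pulse into a 7-mm
#' flat-top spot, two sources, 0.07 x 0.07 mm projected pixel, gated
#' reflection ratio 2.5e-6 at 0.8 ns delay, a 4-mm aperture at 100 mm,
#' 440,000 captured pulses per frame, 0.3 A/W responsivity, 11-ns window.
#'
#' @return a [budget_params()].
#' @export
reference_budget <- function() {
  budget_params(P = 4.8e-10, spot_diameter = 7, n = 2, S = 0.07 * 0.07,
                R_t = 2.5e-6, Omega = solid_angle(4, 100), a = 440000,
                responsivity = 0.3, window = 11)
}

#' Trapezoidal task haemodynamic response
#'
#' Unit-amplitude response: linear rise over `tau` s from task onset,
#' plateau, linear fall over `tau` s after task end.
#'
#' @param t times within a trial (s).
#' @param protocol a [task_protocol()].
#' @param tau ramp time constant (s).
#' @return response values in \[0, 1\].
#' @export
hrf_trapezoid <- function(t, protocol, tau = 5) {
  on <- protocol$rest_before
  off <- on + protocol$task
  pmax(0, pmin(1, (t - on) / tau, (off + tau - t) / tau))
}

#' Generate a synthetic dual-wavelength in-vivo frame stack
#'
#' Forward-projects known ΔHbO·L / ΔHbR·L fields through the extinction
#' matrix to intensities at 750 and 855 nm, applies Poisson shot noise at
#' the budget's electron scale, interleaves the wavelengths into odd/even
#' rows, and attaches matching dark frames. Early- and late-gate channels
#' are returned together with the ground truth for recovery tests.
#'
#' @param spec an [invivo_spec()].
#' @param eps an [extinction_matrix()].
#' @param noise if `FALSE`, frames carry expected electron counts without
#'   Poisson noise (and zero dark), for exact-recovery checks.
#' @return a list: `late` and `early` ([frame_stack()]s, rows interleaved
#'   odd = 750 nm / even = 855 nm), `truth` (list with full-record `time`,
#'   deep-channel `hbo`, `hbr`, superficial `superficial`, amplitude map
#'   `amp_map`, blob-centre pixel `center_px` in full-frame rows/cols),
#'   `spec`.
#' @export
make_invivo_stack <- function(spec = invivo_spec(),
                              eps = extinction_matrix(), noise = TRUE) {
  stopifnot(inherits(spec, "invivo_spec"))
  set.seed(spec$seed)
  pr <- spec$protocol
  fs <- spec$frame_rate
  nfr <- round(pr$trial_s * fs) * pr$n_trials
  tt <- (seq_len(nfr) - 1) / fs
  t_in_trial <- tt %% pr$trial_s

  hrf <- spec$hrf_amp * hrf_trapezoid(t_in_trial, pr, spec$hrf_tau)
  sup <- spec$lfo$amp * sin(2 * pi * spec$lfo$freq * tt) +
    spec$cardiac$amp * sin(2 * pi * spec$cardiac$freq * tt)

  nr <- spec$pixels[1]
  nc <- spec$pixels[2]
  # spatial activation pattern: Gaussian blob at the frame centre
  rr <- outer(seq_len(nr) - (nr + 1) / 2, rep(1, nc))
  ccx <- outer(rep(1, nr), seq_len(nc) - (nc + 1) / 2)
  amp_map <- exp(-(rr^2 + ccx^2) / (2 * (min(nr, nc) / 5)^2))

  N0 <- as.numeric(electron_count(signal_energy(spec$budget),
                                  spec$budget$responsivity))
  stopifnot(N0 > 0)
  lam_row <- ifelse(seq_len(nr) %% 2 == 1, "750", "855")

  build <- function(deep_gain, sup_gain) {
    fr <- array(0, c(nr, nc, nfr))
    for (k in seq_len(nfr)) {
      hbo <- deep_gain * amp_map * hrf[k] + sup_gain * sup[k]
      hbr <- deep_gain * amp_map * spec$hbr_ratio * hrf[k]
      for (lam in c("750", "855")) {
        rows <- which(lam_row == lam)
        dod <- eps[lam, "HbO"] * hbo[rows, , drop = FALSE] +
          eps[lam, "HbR"] * hbr[rows, , drop = FALSE]
        mu <- N0 * exp(-dod)
        if (any(!is.finite(mu)) || any(mu <= 0))
          stop("amplitudes produce non-positive intensities")
        fr[rows, , k] <- if (noise) stats::rpois(length(mu), mu) else mu
      }
    }
    if (noise && spec$dark_mean > 0) {
      dk <- array(stats::rpois(nr * nc * nfr, spec$dark_mean),
                  c(nr, nc, nfr))
      fr <- fr + dk
    } else {
      dk <- array(0, c(nr, nc, nfr))
    }
    frame_stack(fr, fs, dark = dk)
  }

  late <- build(1, spec$superficial_share)
  early <- build(0, 1)
  truth <- list(time = tt, hbo = hrf, hbr = spec$hbr_ratio * hrf,
                superficial = sup, amp_map = amp_map,
                center_px = c(round((nr + 1) / 2), round((nc + 1) / 2)))
  list(late = late, early = early, truth = truth, spec = spec)
}

#' Per-frame pulse ledger
#'
#' Checks the per-frame pulse accounting: `n_wavelengths *
#' pulses_per_switch * repeats` emitted pulses and shutter openings per
#' frame (defaults 2 x 4,000 x 55 = 440,000), and exposes per-wavelength
#' and per-gate counts for budget scaling.
#'
#' @param n_wavelengths wavelengths interleaved per frame.
#' @param pulses_per_switch pulses between wavelength switches.
#' @param repeats switch cycles per frame.
#' @param n_gates gate channels sharing the pulses (early/late taps).
#' @param expected_per_frame optional cross-check; an inconsistent ledger
#'   raises an error.
#' @return a list with `per_frame`, `per_wavelength`, `per_gate`.
#' @export
pulse_accounting <- function(n_wavelengths = 2, pulses_per_switch = 4000,
                             repeats = 55, n_gates = 1,
                             expected_per_frame = NULL) {
  stopifnot(n_wavelengths >= 0, pulses_per_switch >= 0, repeats >= 0,
            n_gates >= 1)
  per_frame <- n_wavelengths * pulses_per_switch * repeats
  if (!is.null(expected_per_frame) && expected_per_frame != per_frame)
    stop(sprintf("inconsistent pulse ledger: %g expected, %g computed",
                 expected_per_frame, per_frame))
  list(per_frame = per_frame,
       per_wavelength = if (n_wavelengths > 0) per_frame / n_wavelengths
                        else 0,
       per_gate = per_frame / n_gates)
}
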