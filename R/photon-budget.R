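#' Elementary charge, coulomb
#' @keywords internal
.elementary_charge <- 1.602176634e-19

#' Solid angle of a circular lens aperture
#'
#' Small-angle approximation `pi * (D/2)^2 / L^2`.
#'
#' @param aperture_diameter lens aperture diameter D (mm).
#' @param distance object-to-lens distance L (mm, > 0).
#' @return solid angle in steradian.
#' @export
solid_angle <- function(aperture_diameter, distance) {
  stopifnot(aperture_diameter >= 0)
  if (distance <= 0) stop("distance must be positive")
  pi * (aperture_diameter / 2)^2 / distance^2
}

#' Signal-budget parameters
#'
#' All quantities entering the per-pixel, per-frame signal energy
#' `Is(t) = (P / spot_area) * n * S * R(t) * Omega / (2 pi) * a`:
#' the single-pulse energy P delivered into a flat-top circular spot,
#' the number of light sources n, the projected pixel area S on the
#' object, the gated reflection ratio R(t), the solid angle Omega to the
#' lens aperture, and the number of captured pulses per frame a.
#'
#' @param P single-pulse energy into the spot (J).
#' @param spot_diameter illumination spot diameter (mm).
#' @param n number of light sources.
#' @param S projected area of one pixel on the object (mm^2).
#' @param R_t gated reflection ratio at the chosen shutter delay.
#' @param Omega solid angle object -> lens aperture (sr, < 2 pi).
#' @param a captured pulses per frame.
#' @param responsivity photodiode responsivity (A/W).
#' @param window shutter window width (ns).
#' @param dark_rate dark-current generation rate (electrons/s) applied
#'   over the per-frame shutter-open time.
#' @return an object of class `budget_params`.
#' @export
budget_params <- function(P, spot_diameter, n, S, R_t, Omega, a,
                          responsivity = 0.3, window = 11,
                          dark_rate = 500) {
  stopifnot(P >= 0, spot_diameter > 0, n >= 0, S >= 0, R_t >= 0,
            Omega >= 0, Omega < 2 * pi, a >= 0, responsivity >= 0,
            window > 0, dark_rate >= 0)
  structure(list(P = P, spot_diameter = spot_diameter, n = n, S = S,
                 R_t = R_t, Omega = Omega, a = a,
                 responsivity = responsivity, window = window,
                 dark_rate = dark_rate),
            class = "budget_params")
}

#' Per-pixel per-frame signal energy
#'
#' @param params a [budget_params()].
#' @return energy in joule.
#' @export
signal_energy <- function(params) {
  stopifnot(inherits(params, "budget_params"))
  spot_area <- pi * (params$spot_diameter / 2)^2
  if (spot_area <= 0) stop("spot area must be positive")
  params$P / spot_area * params$n * params$S * params$R_t *
    params$Omega / (2 * pi) * params$a
}

#' Generated electrons from collected energy
#'
#' `electrons = responsivity * energy / e`. The responsivity in A/W times
#' energy in J gives collected charge in coulomb.
#'
#' @param energy collected energy (J, >= 0).
#' @param responsivity photodiode responsivity (A/W).
#' @return unrounded electron count, with the nearest-integer count as
#'   attribute `"rounded"`.
#' @export
electron_count <- function(energy, responsivity = 0.3) {
  if (energy < 0) stop("energy must be non-negative")
  e <- responsivity * energy / .elementary_charge
  structure(e, rounded = round(e))
}

#' Shot noise of an electron count
#'
#' Shot noise equals the square root of the generated electrons.
#'
#' @param electrons electron count (>= 0).
#' @return unrounded `sqrt(electrons)` with the rounded-down integer as
#'   attribute `"rounded"`.
#' @export
shot_noise <- function(electrons) {
  stopifnot(electrons >= 0)
  s <- sqrt(as.numeric(electrons))
  structure(s, rounded = floor(s))
}

#' Total shutter-open time per frame
#'
#' @param a captured pulses per frame (>= 0).
#' @param window shutter window width (ns).
#' @return open time in seconds.
#' @export
shutter_open_time <- function(a, window = 11) {
  stopifnot(a >= 0, window >= 0)
  a * window * 1e-9
}

#' Measurement sampling density
#'
#' Pixels per square centimetre of the field of view.
#'
#' @param fov field of view, numeric length 2 (mm x mm).
#' @param pixels pixel count, numeric length 2 (cols x rows).
#' @return measurements per cm^2.
#' @export
sampling_density <- function(fov, pixels) {
  stopifnot(length(fov) == 2L, length(pixels) == 2L, all(pixels > 0))
  area_cm2 <- prod(fov) / 100
  if (area_cm2 <= 0) stop("field of view must have positive area")
  prod(pixels) / area_cm2
}

#' Signal and noise report
#'
#' Evaluates the full signal chain of a [budget_params()]: per-pixel
#' energy, generated electrons, shot noise, modelled dark electrons over
#' the shutter-open time, and the resulting SNR
#' `signal / sqrt(signal + dark)`.
#'
#' Two chains are reported: `exact` carries full precision throughout;
#' `printed` rounds the energy to two significant figures before deriving
#' electron counts, reproducing arithmetic chained through
#' two-significant-figure intermediate values.
#'
#' @param params a [budget_params()].
#' @return an object of class `noise_report` (a nested list).
#' @export
noise_report <- function(params) {
  energy <- signal_energy(params)
  open_s <- shutter_open_time(params$a, params$window)
  dark <- params$dark_rate * open_s
  chain <- function(en) {
    ne <- electron_count(en, params$responsivity)
    sn <- shot_noise(ne)
    list(energy_J = as.numeric(en),
         signal_electrons = as.numeric(ne),
         signal_electrons_rounded = attr(ne, "rounded"),
         shot_noise_electrons = as.numeric(sn),
         shot_noise_rounded = attr(sn, "rounded"),
         snr = as.numeric(ne) / sqrt(as.numeric(ne) + dark))
  }
  structure(list(exact = chain(energy),
                 printed = chain(signif(energy, 2)),
                 dark_electrons = dark,
                 shutter_open_s = open_s,
                 params = unclass(params)),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("Per-pixel per-frame energy: %.3g J (printed chain %.2g J)\n",
              x$exact$energy_J, x$printed$energy_J))
  cat(sprintf("Signal electrons: %.4g (rounded %d; printed chain %d)\n",
              x$exact$signal_electrons,
              as.integer(x$exact$signal_electrons_rounded),
              as.integer(x$printed$signal_electrons_rounded)))
  cat(sprintf("Shot noise: %.3g e- (floor %d), dark %.3g e-, SNR %.3g\n",
              x$exact$shot_noise_electrons,
              as.integer(x$exact$shot_noise_rounded),
              x$dark_electrons, x$exact$snr))
  cat(sprintf("Shutter open per frame: %.3g ms\n", x$shutter_open_s * 1e3))
  invisible(x)
}

#' Write a budget report as JSON
#'
#' Echoes every input and derived quantity, at full precision and at two
#' significant figures.
#'
#' @param report a [noise_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_budget_json <- function(report, path) {
  stopifnot(inherits(report, "noise_report"))
  out <- unclass(report)
  out$two_sig_fig <- lapply(out$exact, signif, digits = 2)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
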