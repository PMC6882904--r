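#' Electronic shutter window
#'
#' The gate opens `open_delay` ns after the pulse-off reference (the
#' half-maximum of the falling edge of the surface-reflected pulse; for an
#' ideal square pulse this is the pulse-off instant) and stays open for
#' `width` ns. The shutter is modelled as an ideal top-hat.
#'
#' @param open_delay ns relative to the pulse-off reference.
#' @param width ns (default 11).
#' @return an object of class `shutter_window`.
#' @export
shutter_window <- function(open_delay, width = 11) {
  stopifnot(width > 0)
  structure(list(open_delay = as.numeric(open_delay),
                 width = as.numeric(width)),
            class = "shutter_window")
}

#' Square emission pulse
#'
#' @param width pulse width in ns (rectangular profile).
#' @param fall_time informational fall time in ns (not modelled).
#' @return an object of class `pulse_shape`.
#' @export
pulse_shape <- function(width, fall_time = NULL) {
  stopifnot(width > 0)
  structure(list(width = as.numeric(width), fall_time = fall_time),
            class = "pulse_shape")
}

#' Temporal point spread function (TPSF)
#'
#' Histogram of detected weight per launched unit weight over arrival-time
#' bins. `time_origin` is `"photon_entry"` for impulse responses straight
#' from the simulator and `"pulse_off_edge"` after convolution with an
#' emission pulse. `energy_units` counts the number of impulse-equivalents
#' of input energy the histogram corresponds to (1 for an impulse).
#'
#' @param tally a `photon_tally`, or a numeric vector of per-bin weights.
#' @param bin_width histogram bin width in ns (default 0.025).
#' @param t_max upper time limit in ns (default: max exit time).
#' @param breaks explicit strictly increasing bin edges (overrides
#'   `bin_width`/`t_max`) when `tally` is a numeric weight vector.
#' @param time_origin,energy_units metadata (see above).
#' @return an object of class `tpsf`: `breaks` (edges, ns), `weight`
#'   (per bin), `bin_width`, `time_origin`, `energy_units`.
#' @export
tpsf <- function(tally, bin_width = 0.025, t_max = NULL, breaks = NULL,
                 time_origin = "photon_entry", energy_units = 1) {
  if (inherits(tally, "photon_tally")) {
    ph <- tally$photons
    if (nrow(ph) == 0L) stop("tally contains no detected photons")
    if (is.null(t_max)) t_max <- max(ph$exit_time)
    breaks <- seq(0, t_max + bin_width, by = bin_width)
    idx <- findInterval(ph$exit_time, breaks, rightmost.closed = TRUE)
    w <- as.numeric(
      tapply(ph$weight, factor(idx, levels = seq_len(length(breaks) - 1L)),
             sum, default = 0)) / tally$totals$launched
    time_origin <- "photon_entry"
  } else {
    w <- as.numeric(tally)
    if (is.null(breaks)) breaks <- seq(0, length(w) * bin_width, by = bin_width)
    stopifnot(length(breaks) == length(w) + 1L, all(diff(breaks) > 0))
    bin_width <- breaks[2] - breaks[1]
  }
  stopifnot(all(w >= 0))
  structure(list(breaks = breaks, weight = w,
                 bin_width = breaks[2] - breaks[1],
                 time_origin = match.arg(time_origin,
                                         c("photon_entry", "pulse_off_edge")),
                 energy_units = energy_units,
                 base_breaks = breaks, origin_shift = 0),
            class = "tpsf")
}

#' @export
print.tpsf <- function(x, ...) {
  cat(sprintf(
    "TPSF: %d bins of %g ns, origin %s, total weight %.4g (%g energy units)\n",
    length(x$weight), x$bin_width, x$time_origin, sum(x$weight),
    x$energy_units))
  invisible(x)
}

#' Re-reference a TPSF time origin
#'
#' Shifts the time axis between the photon-entry convention and the
#' pulse-off-edge convention (shift = `pulse_width`, the offset between
#' the start and the end of the emission pulse). Round-tripping is exact.
#'
#' @param x a `tpsf`.
#' @param origin target origin.
#' @param pulse_width emission pulse width in ns.
#' @return a `tpsf` with shifted `breaks` and updated `time_origin`.
#' @export
set_time_origin <- function(x, origin, pulse_width) {
  origin <- match.arg(origin, c("photon_entry", "pulse_off_edge"))
  if (origin == x$time_origin) return(x)
  delta <- if (origin == "pulse_off_edge") -pulse_width else pulse_width
  # track the accumulated shift against the construction-time grid so a
  # round trip restores the breaks bit-for-bit
  x$origin_shift <- x$origin_shift + delta
  x$breaks <- if (x$origin_shift == 0) x$base_breaks
              else x$base_breaks + x$origin_shift
  x$time_origin <- origin
  x
}

#' Convolve an impulse TPSF with a square emission pulse
#'
#' Builds the square-pulse response by superimposition of shifted impulse
#' responses: the output at time t (relative to the pulse-off edge) is the
#' sum of impulse contributions from every emission instant within the
#' pulse. At fixed peak power the pulse carries `width / impulse_width`
#' impulse-equivalents of energy, so the total output weight scales by
#' that factor (`energy_units` of the result).
#'
#' @param impulse a `tpsf` with `time_origin = "photon_entry"`.
#' @param pulse a [pulse_shape()] or pulse width in ns.
#' @param impulse_width reference impulse duration defining one unit of
#'   input energy (ns; default 0.01, i.e. 10 ps).
#' @return a `tpsf` with `time_origin = "pulse_off_edge"`.
#' @export
convolve_pulse <- function(impulse, pulse, impulse_width = 0.01) {
  stopifnot(inherits(impulse, "tpsf"))
  if (impulse$time_origin != "photon_entry")
    stop("impulse TPSF must have time_origin = 'photon_entry'")
  width <- if (inherits(pulse, "pulse_shape")) pulse$width else pulse
  dt <- impulse$bin_width
  if (width < dt)
    stop("pulse width is below the TPSF bin width; re-bin the TPSF finer")
  M <- max(1L, as.integer(round(width / dt)))
  h <- impulse$weight
  J <- length(h)
  cs <- cumsum(c(0, h))
  i <- seq_len(J + M - 1L)
  s <- cs[pmin(J, i) + 1L] - cs[pmax(1L, i - M + 1L)]
  s <- s * (dt / impulse_width)
  # impulse mass at bin centre c spreads uniformly over arrivals
  # [c - width, c]; the output bin holding shift k = i - j is centred at
  # c + (k - M + 1) * dt - dt/2, so the output grid sits half a bin early
  new_breaks <- impulse$breaks[1] +
    (seq(0L, J + M - 1L) - (M - 1L)) * dt - dt / 2
  tpsf(s, breaks = new_breaks, time_origin = "pulse_off_edge",
       energy_units = impulse$energy_units * width / impulse_width)
}

# cumulative weight up to time tq (linear interpolation within bins)
.tpsf_cum <- function(x, tq) {
  br <- x$breaks
  cw <- c(0, cumsum(x$weight))
  tq <- pmin(pmax(tq, br[1]), br[length(br)])
  i <- findInterval(tq, br, rightmost.closed = TRUE)
  frac <- (tq - br[i]) / (br[i + 1] - br[i])
  frac[i >= length(br)] <- 0
  cw[i] + x$weight[pmin(i, length(x$weight))] * frac
}

#' Gated detected fraction
#'
#' Detected weight within the shutter window \[t, t + width\] per launched
#' unit weight, linearly interpolating partial bins. Monotone
#' non-increasing in the open delay (for delays past the peak support) and
#' non-decreasing in the window width.
#'
#' @param x a `tpsf` with `time_origin = "pulse_off_edge"`.
#' @param window a [shutter_window()], or the open delay in ns.
#' @param width window width in ns when `window` is numeric.
#' @return the gated weight (same energy units as `x`). A window entirely
#'   outside the histogram support returns 0 with a warning.
#' @export
gated_fraction <- function(x, window, width = 11) {
  stopifnot(inherits(x, "tpsf"))
  if (x$time_origin != "pulse_off_edge")
    stop("TPSF must be referenced to the pulse-off edge; see set_time_origin()")
  if (inherits(window, "shutter_window")) {
    width <- window$width
    window <- window$open_delay
  }
  t0 <- window
  t1 <- window + width
  br <- x$breaks
  if (t1 <= br[1] || t0 >= br[length(br)]) {
    warning("shutter window lies entirely outside the TPSF support")
    return(0)
  }
  .tpsf_cum(x, t1) - .tpsf_cum(x, t0)
}

#' Superimposition gain
#'
#' Ratio of the gated signal under square-pulse illumination to the gated
#' signal under impulse illumination at equal input power (so the square
#' pulse carries `width / impulse_width` times the energy). For any TPSF
#' with a decaying tail the ratio is >= 1.
#'
#' @param impulse_gated gated fraction of the impulse response (1 energy
#'   unit).
#' @param square_gated gated fraction of the square-pulse response in its
#'   own energy units (i.e. as returned by [gated_fraction()] on a
#'   [convolve_pulse()] result).
#' @return the ratio; `Inf` if the impulse gated fraction is 0.
#' @export
superimposition_gain <- function(impulse_gated, square_gated) {
  stopifnot(impulse_gated >= 0, square_gated >= 0)
  if (impulse_gated == 0) return(Inf)
  square_gated / impulse_gated
}

#' Per-photon gated weight under square-pulse emission
#'
#' For a photon with transit time `tau` (ns from its own emission) and a
#' square emission pulse of width `pulse_width` ending at time 0, the
#' emission offsets for which the photon arrives inside the gate
#' \[delay, delay + width\] form an interval; its length divided by
#' `impulse_width` is the photon's gate weight in impulse-equivalent
#' energy units. Summing `weight * square_gate_weight(...)` over a tally
#' and dividing by the launched weight reproduces the gated fraction of
#' the convolved TPSF without binning error.
#'
#' @param tau photon transit times (ns, origin photon entry); vectorized.
#' @param delay,width shutter open delay and width (ns, relative to
#'   pulse-off).
#' @param pulse_width emission pulse width (ns).
#' @param impulse_width reference impulse duration (ns, default 0.01).
#' @return numeric vector of gate weights.
#' @export
square_gate_weight <- function(tau, delay, width, pulse_width,
                               impulse_width = 0.01) {
  lo <- pmax(delay - tau, -pulse_width)
  hi <- pmin(delay + width - tau, 0)
  pmax(hi - lo, 0) / impulse_width
}

#' Sample square-pulse emission times onto an impulse tally
#'
#' Monte Carlo alternative to [convolve_pulse()]: draws one emission
#' instant uniformly within the square pulse for each detected photon and
#' re-references exit times to the pulse-off edge. The per-photon weights
#' are unchanged, so weighted averages (e.g. partial-path curves) and
#' gated fractions per unit total pulse energy follow directly.
#'
#' @param tally a `photon_tally` with `time_origin = "photon_entry"`.
#' @param pulse_width square pulse width (ns).
#' @param seed integer seed for the emission-time draws.
#' @return the tally with shifted `exit_time` and
#'   `time_origin = "pulse_off_edge"`.
#' @export
sample_emission_times <- function(tally, pulse_width, seed = 1) {
  stopifnot(inherits(tally, "photon_tally"),
            tally$time_origin == "photon_entry", pulse_width > 0)
  set.seed(seed)
  tally$photons$exit_time <- tally$photons$exit_time -
    stats::runif(nrow(tally$photons), 0, pulse_width)
  tally$time_origin <- "pulse_off_edge"
  tally
}

#' Gated reflection ratio R(t)
#'
#' The ratio of gated detected light intensity to input light intensity
#' per unit area: the gated detected energy fraction (per unit total pulse
#' energy) scaled by the illuminated-to-detector area ratio, so that a
#' uniform wide-field input of fluence E/A yields a gated exitance of
#' R(t) * E/A at the detector position. This is the R(t) entering the
#' per-pixel signal budget.
#'
#' @param tally a `photon_tally` from an impulse simulation.
#' @param window a [shutter_window()] (delay relative to pulse-off).
#' @param pulse a [pulse_shape()] or pulse width in ns.
#' @return the ratio, with the Monte Carlo standard error as attribute
#'   `"se"` and the summed gate weight count as attribute `"n"`.
#' @export
gated_reflection_ratio <- function(tally, window, pulse) {
  stopifnot(inherits(tally, "photon_tally"),
            inherits(window, "shutter_window"))
  pw <- if (inherits(pulse, "pulse_shape")) pulse$width else pulse
  ph <- tally$photons
  # per-photon gated path-time overlap in ns (impulse_width cancels in the
  # per-unit-energy normalisation, so use 1 ns as the unit here)
  g <- square_gate_weight(ph$exit_time, window$open_delay, window$width,
                          pw, impulse_width = 1)
  x <- ph$weight * g / pw # fraction of total pulse energy per photon
  N <- tally$totals$launched
  area_ratio <- rect_area(tally$source) / rect_area(tally$detector)
  val <- sum(x) / N * area_ratio
  se <- sqrt(max(sum(x^2) - sum(x)^2 / N, 0)) / N * area_ratio
  structure(val, se = se, n = sum(g > 0))
}

#' Read or write a TPSF as two-column CSV
#'
#' The file holds comment header lines recording the time origin, bin
#' width and energy units, then `time,weight` rows (bin centres in ns).
#'
#' @param x a `tpsf`.
#' @param path file path.
#' @return `write_tpsf()` returns `path` invisibly; `read_tpsf()` returns
#'   a `tpsf`.
#' @export
write_tpsf <- function(x, path) {
  stopifnot(inherits(x, "tpsf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# time_origin=%s", x$time_origin),
               sprintf("# bin_width=%.17g", x$bin_width),
               sprintf("# energy_units=%.17g", x$energy_units),
               "time,weight"), con)
  centers <- x$breaks[-length(x$breaks)] + x$bin_width / 2
  utils::write.table(data.frame(time = centers, weight = x$weight), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tpsf
#' @export
read_tpsf <- function(path) {
  hdr <- readLines(path, n = 3L)
  kv <- function(l) sub("# [a-z_]+=", "", l)
  origin <- kv(hdr[1])
  bw <- as.numeric(kv(hdr[2]))
  eu <- as.numeric(kv(hdr[3]))
  d <- utils::read.csv(path, comment.char = "#")
  breaks <- c(d$time - bw / 2, d$time[length(d$time)] + bw / 2)
  tpsf(d$weight, breaks = breaks, time_origin = origin, energy_units = eu)
}
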