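#' Dual-wavelength interleaved frame stack
#'
#' Frames are stored as a 3-D array `[row, col, frame]`. Odd and even row
#' lines carry the two wavelengths (alternating every 4,000 pulses on the
#' sensor), recorded in `row_parity`; `dark` holds matching background
#' captures taken without illumination.
#'
#' @param frames numeric 3-D array `[row, col, frame]`.
#' @param frame_rate frames per second (default 5).
#' @param row_parity named character vector mapping `odd`/`even` rows to
#'   wavelength labels.
#' @param dark optional matching 3-D array (or a single matrix recycled
#'   over frames) of background captures.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate = 5,
                        row_parity = c(odd = "750", even = "855"),
                        dark = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[3] >= 1L, frame_rate > 0,
            all(c("odd", "even") %in% names(row_parity)))
  if (!is.null(dark)) {
    if (is.matrix(dark)) dark <- array(dark, dim = dim(frames))
    stopifnot(all(dim(dark) == dim(frames)))
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 row_parity = row_parity, dark = dark),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Frame stack: %d x %d px, %d frames at %g fps (%.1f s), rows odd=%s even=%s%s\n",
    d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate,
    x$row_parity[["odd"]], x$row_parity[["even"]],
    if (is.null(x$dark)) "" else ", dark frames attached"))
  invisible(x)
}

#' De-interleave a dual-wavelength stack
#'
#' Splits the odd and even row lines into two single-wavelength stacks at
#' half the vertical resolution. An odd total row count drops the last
#' unpaired row with a warning. Row provenance (original row indices) is
#' recorded as an attribute on each output.
#'
#' @param stack a [frame_stack()].
#' @return a named list of two `frame_stack`s keyed by wavelength label.
#' @export
deinterleave <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  nr <- dim(stack$frames)[1]
  use <- nr
  if (nr %% 2L == 1L) {
    warning("odd row count; dropping the last unpaired row")
    use <- nr - 1L
  }
  odd <- seq(1L, use, by = 2L)
  even <- seq(2L, use, by = 2L)
  pick <- function(rows) {
    fs <- frame_stack(stack$frames[rows, , , drop = FALSE],
                      stack$frame_rate, stack$row_parity,
                      if (is.null(stack$dark)) NULL
                      else stack$dark[rows, , , drop = FALSE])
    attr(fs, "source_rows") <- rows
    fs
  }
  out <- list(pick(odd), pick(even))
  names(out) <- c(stack$row_parity[["odd"]], stack$row_parity[["even"]])
  out
}

#' Subtract background (dark) frames
#'
#' @param stack a [frame_stack()].
#' @param dark 3-D array or matrix of background captures; defaults to the
#'   stack's own `dark` component.
#' @param floor negative results are clipped to this value (default 0).
#' @return a `frame_stack` with the background removed and `dark = NULL`.
#' @export
subtract_background <- function(stack, dark = stack$dark, floor = 0) {
  stopifnot(inherits(stack, "frame_stack"), !is.null(dark))
  if (is.matrix(dark)) dark <- array(dark, dim = dim(stack$frames))
  if (!all(dim(dark) == dim(stack$frames)))
    stop("dark frame dimensions do not match the signal stack")
  out <- stack$frames - dark
  out[out < floor] <- floor
  frame_stack(out, stack$frame_rate, stack$row_parity, dark = NULL)
}

#' Per-pixel ΔOD time series
#'
#' `ΔOD(t) = -ln(I(t) / mean(I_baseline))` per pixel. Pixels whose
#' baseline mean or instantaneous intensity is non-positive are flagged
#' invalid (`NA`).
#'
#' @param stack a single-wavelength [frame_stack()].
#' @param baseline_frames integer frame indices of the baseline window
#'   (default: the first frame).
#' @return a 3-D array `[row, col, frame]` of ΔOD values with attribute
#'   `frame_rate`.
#' @export
delta_od_series <- function(stack, baseline_frames = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  base <- apply(fr[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  out <- array(NA_real_, dim(fr))
  ok <- base > 0
  for (k in seq_len(dim(fr)[3])) {
    f <- fr[, , k]
    v <- -log(f / base)
    v[!ok | f <= 0] <- NA_real_
    out[, , k] <- v
  }
  attr(out, "frame_rate") <- stack$frame_rate
  out
}

#' Haemoglobin extinction matrix
#'
#' 2x2 matrix of extinction coefficients, rows = wavelengths (750, 855 nm),
#' columns = species (HbO, HbR), in natural-log units of mm^-1 mM^-1.
#' Defaults derive from the standard compiled haemoglobin absorption
#' spectra (molar log10 extinction converted by ln 10 and to per-mm):
#' at 750 nm deoxy-haemoglobin dominates, at 855 nm oxy-haemoglobin does.
#'
#' @param values optional 2x2 numeric matrix overriding the defaults.
#' @return the matrix with dimnames, condition number as attribute
#'   `"condition"`.
#' @export
extinction_matrix <- function(values = NULL) {
  if (is.null(values)) {
    values <- log(10) * 1e-1 *
      matrix(c(0.518, 1.405,   # 750 nm: HbO, HbR (mM^-1 cm^-1, log10)
               1.058, 0.692),  # 855 nm
             nrow = 2, byrow = TRUE)
  }
  stopifnot(is.matrix(values), all(dim(values) == 2L))
  dimnames(values) <- list(c("750", "855"), c("HbO", "HbR"))
  attr(values, "condition") <- kappa(values, exact = TRUE)
  values
}

#' Modified Beer-Lambert two-wavelength inversion
#'
#' Solves the per-pixel, per-frame 2x2 linear system
#' `ΔOD(λ) = ε(λ, HbO) ΔHbO·L + ε(λ, HbR) ΔHbR·L` for the products of
#' concentration change and optical path length (mM·mm). No differential
#' pathlength factor is applied.
#'
#' @param dod750,dod855 ΔOD values at the two wavelengths (equal-shaped
#'   numerics, vectors or arrays).
#' @param eps an [extinction_matrix()].
#' @param max_condition inversion refused above this condition number.
#' @return a list with `hbo` and `hbr` shaped like the inputs.
#' @export
mbll_invert <- function(dod750, dod855, eps = extinction_matrix(),
                        max_condition = 1e6) {
  stopifnot(all(dim(dod750) == dim(dod855)),
            length(dod750) == length(dod855))
  kap <- attr(eps, "condition") %||% kappa(eps, exact = TRUE)
  if (kap > max_condition)
    stop(sprintf("extinction matrix is ill-conditioned (condition %.3g)", kap))
  inv <- solve(eps)
  hbo <- inv[1, 1] * dod750 + inv[1, 2] * dod855
  hbr <- inv[2, 1] * dod750 + inv[2, 2] * dod855
  list(hbo = hbo, hbr = hbr)
}

#' Zero-phase band-pass filter
#'
#' 3rd-order Butterworth applied forward and backward (zero phase); the
#' pass band must lie strictly inside (0, fs/2). DC is rejected.
#'
#' @param x numeric vector, or matrix with time along rows.
#' @param f_lo,f_hi band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param order filter order (default 3).
#' @return filtered series, same shape as `x`.
#' @export
bandpass <- function(x, f_lo = 0.01, f_hi = 0.1, fs, order = 3) {
  if (!(0 < f_lo && f_lo < f_hi && f_hi < fs / 2))
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  f1 <- function(v) as.numeric(signal::filtfilt(bf, v - mean(v)))
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Anchored linear baseline correction
#'
#' Fits a straight line through the series' means in short windows
#' centred at the anchor times and subtracts it, anchoring the baseline
#' at, e.g., the pre-task rest (30 s) and end of record (85 s).
#'
#' @param x numeric vector (one time series).
#' @param fs sampling rate (Hz).
#' @param anchors anchor times in seconds (length 2), within the record.
#' @param half_window half-width of each anchor window (s, default 2).
#' @return the corrected series.
#' @export
baseline_correct <- function(x, fs, anchors = c(30, 85), half_window = 2) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  stopifnot(length(anchors) == 2L)
  if (any(anchors < 0 | anchors > tt[n] + 1 / fs))
    stop("anchor time outside the record")
  m <- vapply(anchors, function(a) {
    w <- which(tt >= a - half_window & tt <= a + half_window)
    if (length(w) == 0) stop("empty anchor window")
    mean(x[w])
  }, 0)
  slope <- (m[2] - m[1]) / (anchors[2] - anchors[1])
  x - (m[1] + slope * (tt - anchors[1]))
}

#' Block-task protocol
#'
#' @param rest_before,task,rest_after durations in seconds.
#' @param n_trials number of trials.
#' @return an object of class `task_protocol`.
#' @export
task_protocol <- function(rest_before = 30, task = 25, rest_after = 30,
                          n_trials = 5) {
  stopifnot(rest_before > 0, task > 0, rest_after > 0, n_trials >= 1)
  structure(list(rest_before = rest_before, task = task,
                 rest_after = rest_after, n_trials = as.integer(n_trials),
                 trial_s = rest_before + task + rest_after),
            class = "task_protocol")
}

#' Haemoglobin time series for one trial
#'
#' @param time times in seconds.
#' @param hbo,hbr ΔHbO·L and ΔHbR·L series (mM·mm).
#' @return an object of class `haemo_series`.
#' @export
haemo_series <- function(time, hbo, hbr) {
  stopifnot(length(time) == length(hbo), length(hbo) == length(hbr),
            all(is.finite(hbo)), all(is.finite(hbr)))
  structure(list(time = time, hbo = hbo, hbr = hbr),
            class = "haemo_series")
}

#' Split a series into per-trial segments
#'
#' @param hbo,hbr full-record series.
#' @param fs sampling rate (Hz).
#' @param protocol a [task_protocol()].
#' @return a list of [haemo_series()], one per trial (trial-local time).
#' @export
split_trials <- function(hbo, hbr, fs, protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  per <- round(protocol$trial_s * fs)
  stopifnot(length(hbo) >= per * protocol$n_trials)
  lapply(seq_len(protocol$n_trials), function(k) {
    i <- (k - 1L) * per + seq_len(per)
    haemo_series((seq_len(per) - 1) / fs, hbo[i], hbr[i])
  })
}

#' Normalized trial averaging
#'
#' Divides each trial by its own maximum ΔHbO·L (trials with a
#' non-positive maximum are excluded with a warning), then returns the
#' pointwise mean and standard error (sd/sqrt(n)) of the normalized
#' trials.
#'
#' @param trials a list of equal-length [haemo_series()].
#' @return a list with `time`, `hbo`, `hbr`, `hbo_se`, `hbr_se`, `n`.
#' @export
trial_average <- function(trials) {
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, inherits, TRUE, "haemo_series")))
  len <- vapply(trials, function(t) length(t$hbo), 0L)
  stopifnot(all(len == len[1]))
  mx <- vapply(trials, function(t) max(t$hbo), 0)
  keep <- mx > 0
  if (!any(keep)) {
    # degenerate record (e.g. an all-zero series): average unnormalized
    warning("all trials have non-positive max HbO; averaging without normalization")
    mx <- rep(1, length(trials))
  } else if (!all(keep)) {
    warning(sprintf("%d trial(s) with non-positive max HbO excluded",
                    sum(!keep)))
    trials <- trials[keep]
    mx <- mx[keep]
  }
  ho <- sapply(seq_along(trials), function(i) trials[[i]]$hbo / mx[i])
  hr <- sapply(seq_along(trials), function(i) trials[[i]]$hbr / mx[i])
  n <- length(trials)
  se <- function(m) if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else
    rep(0, nrow(m))
  list(time = trials[[1]]$time, hbo = rowMeans(ho), hbr = rowMeans(hr),
       hbo_se = se(ho), hbr_se = se(hr), n = n)
}

#' Normalized power spectrum
#'
#' Periodogram of a detrended series normalized to unit maximum.
#'
#' @param x numeric series (length >= 16).
#' @param fs sampling rate (Hz).
#' @return a data.frame with `freq` (Hz) and `power` (max = 1). A constant
#'   series is flagged degenerate (attribute `"degenerate"`, all-zero
#'   power) with a warning.
#' @export
power_spectrum <- function(x, fs) {
  stopifnot(length(x) >= 16L)
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2)
  freq <- (seq_len(nf)) * fs / n
  p <- p[seq_len(nf) + 1L]
  out <- data.frame(freq = freq, power = p)
  if (max(p) <= 0 || !is.finite(max(p))) {
    warning("constant series: degenerate spectrum")
    out$power <- 0
    attr(out, "degenerate") <- TRUE
  } else {
    out$power <- p / max(p)
    attr(out, "degenerate") <- FALSE
  }
  out
}

#' Write a haemoglobin series (or trial average) as CSV
#'
#' @param x a [haemo_series()] or [trial_average()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haemo_csv <- function(x, path) {
  df <- as.data.frame(x[intersect(names(x),
                                  c("time", "hbo", "hbr", "hbo_se",
                                    "hbr_se"))])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
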