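test_that("square-pulse convolution reproduces the rectangle and conserves energy", {
  bw <- 0.025
  h <- c(rep(0, 10), 1, rep(0, 29)) * 0.5 # all weight in one bin
  ts <- tpsf(h, breaks = seq(0, length(h)) * bw)
  sq <- convolve_pulse(ts, 11)
  # flat plateau of 11 ns duration
  plateau <- sq$weight[sq$weight > 0]
  expect_equal(length(plateau), round(11 / bw))
  expect_true(all(abs(plateau - plateau[1]) < 1e-12))
  # total weight scales by the number of impulse-equivalents (11 ns / 10 ps)
  expect_equal(sum(sq$weight) / sum(ts$weight), 1100, tolerance = 1e-9)
  expect_equal(sq$energy_units, 1100)
  expect_identical(sq$time_origin, "pulse_off_edge")
})

test_that("one-bin pulse width reduces to an origin shift", {
  bw <- 0.025
  set.seed(1)
  h <- runif(40)
  ts <- tpsf(h, breaks = seq(0, 40) * bw)
  sq <- convolve_pulse(ts, bw, impulse_width = bw)
  expect_equal(sq$weight, ts$weight, tolerance = 1e-12)
  expect_error(convolve_pulse(ts, bw / 4), "bin width")
})

test_that("gated fraction integrates the window with partial-bin interpolation", {
  bw <- 0.1
  h <- rep(1, 50) # uniform density
  ts <- tpsf(h, breaks = seq(0, 50) * bw, time_origin = "pulse_off_edge")
  # full support
  expect_equal(gated_fraction(ts, 0, width = 5), 50)
  # partial bins interpolate linearly
  expect_equal(gated_fraction(ts, 0.05, width = 0.1), 1, tolerance = 1e-12)
  expect_equal(gated_fraction(ts, 1.23, width = 2.5), 25, tolerance = 1e-9)
  # window past the last bin: zero with a warning
  expect_warning(z <- gated_fraction(ts, 99, width = 11), "outside")
  expect_equal(z, 0)
  # origin guard
  ts2 <- tpsf(h, breaks = seq(0, 50) * bw)
  expect_error(gated_fraction(ts2, 0), "pulse-off")
})

test_that("gated fraction is monotone in delay and in width", {
  tl <- table1_tally()
  sq <- convolve_pulse(tpsf(tl, bin_width = 0.025), 11)
  delays <- seq(0.2, 2, by = 0.2)
  g <- vapply(delays, function(d) gated_fraction(sq, d, width = 11), 0)
  expect_true(all(diff(g) <= 0))
  widths <- c(1, 3, 6, 11, 20)
  gw <- vapply(widths, function(w) gated_fraction(sq, 0.8, width = w), 0)
  expect_true(all(diff(gw) >= 0))
})

test_that("time-origin re-referencing round-trips exactly", {
  h <- runif(30)
  ts <- tpsf(h, breaks = seq(0, 30) * 0.025)
  back <- set_time_origin(set_time_origin(ts, "pulse_off_edge", 11),
                          "photon_entry", 11)
  expect_identical(back$breaks, ts$breaks)
  expect_identical(back$time_origin, ts$time_origin)
})

test_that("convolution agrees with emission-time sampling and the analytic gate", {
  tl <- table1_tally()
  win <- shutter_window(0.8, 11)
  sq <- convolve_pulse(tpsf(tl, bin_width = 0.025), 11)
  g_conv <- gated_fraction(sq, win) / sq$energy_units # per unit pulse energy
  # analytic per-photon emission-interval overlap
  ph <- tl$photons
  g_exact <- sum(ph$weight *
                   square_gate_weight(ph$exit_time, 0.8, 11, 11, 1)) / 11 /
    tl$totals$launched
  expect_equal(g_conv, g_exact, tolerance = 0.02)
  # Monte Carlo emission-time sampling
  st <- sample_emission_times(tl, 11, seed = 99)
  x <- ph$weight * (st$photons$exit_time >= 0.8 &
                      st$photons$exit_time <= 11.8)
  g_mc <- sum(x) / tl$totals$launched
  se <- sqrt(max(sum(x^2) - sum(x)^2 / tl$totals$launched, 0)) /
    tl$totals$launched
  expect_lt(abs(g_mc - g_exact), 3 * se + 1e-15)
})

test_that("superimposition gain matches the closed form for an exponential tail", {
  tau <- 1
  bw <- 0.005
  tt <- seq(0, 14, by = bw)
  h <- exp(-(tt[-1] - bw / 2) / tau) * bw / tau
  ts <- tpsf(h, breaks = tt)
  sq <- convolve_pulse(ts, 11)
  gi <- gated_fraction(set_time_origin(ts, "pulse_off_edge", 0.01),
                       shutter_window(0.5, 11))
  gs <- gated_fraction(sq, shutter_window(0.5, 11))
  gain <- superimposition_gain(gi, gs)
  closed <- (tau / 0.01) * (1 - exp(-11 / tau))
  expect_equal(gain, closed, tolerance = 0.02)
  # identical pulses give unit ratio; a zero impulse reference is flagged
  expect_equal(superimposition_gain(0.3, 0.3), 1)
  expect_identical(superimposition_gain(0, 0.1), Inf)
})

test_that("TPSF CSV round-trips with its header metadata", {
  tl <- table1_tally()
  ts <- convolve_pulse(tpsf(tl, bin_width = 0.05), 11)
  tf <- tempfile(fileext = ".csv")
  write_tpsf(ts, tf)
  back <- read_tpsf(tf)
  expect_equal(back$weight, ts$weight, tolerance = 1e-12)
  expect_equal(back$breaks, ts$breaks, tolerance = 1e-9)
  expect_identical(back$time_origin, ts$time_origin)
  expect_equal(back$energy_units, ts$energy_units)
})

test_that("reflection-ratio routes agree and carry a standard error", {
  tl <- table1_tally()
  win <- shutter_window(0.8, 11)
  r <- gated_reflection_ratio(tl, win, pulse_shape(11))
  sq <- convolve_pulse(tpsf(tl, bin_width = 0.025), 11)
  area_ratio <- 64 * 18 / 100
  r_tpsf <- gated_fraction(sq, win) / sq$energy_units * area_ratio
  expect_equal(as.numeric(r), r_tpsf, tolerance = 0.03)
  expect_gt(attr(r, "se"), 0)
  expect_lt(attr(r, "se") / as.numeric(r), 0.1)
})
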