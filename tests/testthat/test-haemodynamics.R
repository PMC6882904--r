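make_stack <- function(frames, fr = 5, dark = NULL)
  frame_stack(frames, fr, dark = dark)

test_that("de-interleaving separates row parities and round-trips", {
  fr <- array(0, c(6, 4, 3))
  fr[c(1, 3, 5), , ] <- 1
  fr[c(2, 4, 6), , ] <- 2
  st <- make_stack(fr)
  out <- deinterleave(st)
  expect_named(out, c("750", "855"))
  expect_true(all(out[["750"]]$frames == 1))
  expect_true(all(out[["855"]]$frames == 2))
  # constant input stays constant in both outputs
  cst <- make_stack(array(7, c(6, 4, 2)))
  oc <- deinterleave(cst)
  expect_true(all(oc[["750"]]$frames == 7) && all(oc[["855"]]$frames == 7))
  # round trip reconstructs the original exactly
  set.seed(1)
  rnd <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  o <- deinterleave(make_stack(rnd))
  rebuilt <- array(NA_real_, dim(rnd))
  rebuilt[attr(o[["750"]], "source_rows"), , ] <- o[["750"]]$frames
  rebuilt[attr(o[["855"]], "source_rows"), , ] <- o[["855"]]$frames
  expect_identical(rebuilt, rnd)
  # odd row counts drop the last row with a warning
  expect_warning(o2 <- deinterleave(make_stack(array(1, c(5, 4, 2)))),
                 "unpaired")
  expect_equal(dim(o2[["750"]]$frames)[1], 2L)
})

test_that("background subtraction is element-wise, clipped and linear", {
  set.seed(2)
  sig <- array(runif(24, 10, 20), c(2, 3, 4))
  drk <- array(runif(24, 0, 5), c(2, 3, 4))
  st <- make_stack(sig)
  expect_equal(subtract_background(st, array(0, dim(sig)))$frames, sig)
  expect_true(all(subtract_background(st, sig)$frames == 0))
  once_twice <- subtract_background(subtract_background(st, drk), drk)
  at_once <- subtract_background(st, 2 * drk)
  expect_equal(once_twice$frames, at_once$frames)
  expect_error(subtract_background(st, array(0, c(3, 3, 4))), "dimensions")
  # negatives clip to the floor
  clipped <- subtract_background(st, sig + 1)
  expect_true(all(clipped$frames == 0))
})

test_that("ΔOD series has the Beer-Lambert closed forms and scale invariance", {
  base <- array(100, c(2, 2, 5))
  st <- make_stack(base)
  expect_true(all(delta_od_series(st, 1:2) == 0))
  fr <- base
  fr[, , 3] <- 100 / exp(1)
  expect_equal(delta_od_series(make_stack(fr), 1)[1, 1, 3], 1,
               tolerance = 1e-12)
  expect_equal(delta_od_series(make_stack(2 * fr), 1),
               delta_od_series(make_stack(fr), 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # non-positive intensities flag the pixel invalid
  fr[1, 1, 2] <- 0
  expect_true(is.na(delta_od_series(make_stack(fr), 1)[1, 1, 2]))
})

test_that("MBLL inversion round-trips and has the right sign structure", {
  eps <- extinction_matrix()
  expect_lt(attr(eps, "condition"), 20)
  # deoxy dominates at 750 nm, oxy at 855 nm
  expect_gt(eps["750", "HbR"], eps["750", "HbO"])
  expect_gt(eps["855", "HbO"], eps["855", "HbR"])
  set.seed(4)
  hbo <- rnorm(50)
  hbr <- rnorm(50)
  dod750 <- eps["750", "HbO"] * hbo + eps["750", "HbR"] * hbr
  dod855 <- eps["855", "HbO"] * hbo + eps["855", "HbR"] * hbr
  rec <- mbll_invert(dod750, dod855, eps)
  expect_equal(rec$hbo, hbo, tolerance = 1e-12)
  expect_equal(rec$hbr, hbr, tolerance = 1e-12)
  expect_equal(mbll_invert(0, 0, eps), list(hbo = 0, hbr = 0))
  # raising ΔOD at 855 nm alone raises the oxy estimate
  up <- mbll_invert(0.1, 0.3, eps)
  base <- mbll_invert(0.1, 0.2, eps)
  expect_gt(up$hbo, base$hbo)
  # ill-conditioned matrices are refused by name
  bad <- matrix(c(1, 1, 1, 1 + 1e-12), 2)
  expect_error(mbll_invert(0.1, 0.1, extinction_matrix(bad)),
               "ill-conditioned")
})

test_that("band-pass rejects DC and stop band while passing the band", {
  fs <- 5
  t <- seq(0, 200 - 1 / fs, by = 1 / fs)
  expect_lt(max(abs(bandpass(rep(3, length(t)), 0.01, 0.1, fs))), 1e-8)
  inband <- sin(2 * pi * 0.05 * t)
  out <- bandpass(inband, 0.01, 0.1, fs)
  mid <- seq(200, length(t) - 200)
  amp <- max(abs(out[mid]))
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.05)
  stopb <- sin(2 * pi * 1.1 * t)
  expect_lt(max(abs(bandpass(stopb, 0.01, 0.1, fs)[mid])), 0.05)
  expect_error(bandpass(inband, 0.01, 3, fs), "fs/2")
})

test_that("anchored baseline correction removes linear drift and is affine-safe", {
  fs <- 5
  n <- 100 * fs # anchors at 30 s and 85 s sit well inside the record
  t <- (seq_len(n) - 1) / fs
  drift <- 0.4 + 0.02 * t
  expect_lt(max(abs(baseline_correct(drift, fs))), 1e-10)
  sig <- sin(2 * pi * 0.05 * t)
  zeroed <- sig - mean(sig[abs(t - 30) <= 2]) -
    (t - 30) * (mean(sig[abs(t - 85) <= 2]) - mean(sig[abs(t - 30) <= 2])) /
      55
  expect_equal(baseline_correct(sig, fs), zeroed, tolerance = 1e-10)
  # adding a constant changes nothing after correction
  expect_equal(baseline_correct(sig + 5, fs), baseline_correct(sig, fs),
               tolerance = 1e-10)
  expect_error(baseline_correct(sig, fs, anchors = c(30, 200)), "outside")
})

test_that("normalized trial averaging has the stated degeneracies", {
  t <- seq(0, 10, by = 0.2)
  tr <- haemo_series(t, sin(t) + 1.5, -0.3 * sin(t))
  same <- trial_average(list(tr, tr, tr))
  expect_true(all(same$hbo_se == 0))
  expect_equal(max(same$hbo), 1)
  one <- trial_average(list(tr))
  expect_equal(one$hbo, tr$hbo / max(tr$hbo))
  expect_true(all(one$hbo_se == 0))
  # scalar multiples normalize to the same trial
  tr2 <- haemo_series(t, 3 * tr$hbo, 3 * tr$hbr)
  pair <- trial_average(list(tr, tr2))
  expect_true(all(abs(pair$hbo_se) < 1e-12))
  # non-positive-maximum trials are excluded with a warning
  flat <- haemo_series(t, rep(-1, length(t)), rep(0, length(t)))
  expect_warning(mix <- trial_average(list(tr, flat)), "excluded")
  expect_equal(mix$n, 1)
})

test_that("power spectra are unit-normalized with correct peak structure", {
  fs <- 5
  n <- 500
  t <- (seq_len(n) - 1) / fs
  s <- power_spectrum(sin(2 * pi * 0.1 * t), fs)
  expect_equal(s$freq[which.max(s$power)], 0.1)
  expect_equal(max(s$power), 1)
  # half-amplitude secondary tone carries a quarter of the power
  s2 <- power_spectrum(sin(2 * pi * 0.1 * t) +
                         0.5 * sin(2 * pi * 1.1 * t), fs)
  expect_equal(s2$power[which.min(abs(s2$freq - 1.1))], 0.25,
               tolerance = 0.01)
  set.seed(5)
  sw <- power_spectrum(rnorm(n), fs)
  expect_true(all(sw$power <= 1))
  expect_warning(sd <- power_spectrum(rep(2, 32), fs), "degenerate")
  expect_true(attr(sd, "degenerate"))
})
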