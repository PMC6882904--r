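test_that("a zero absorption change renders an identically zero image", {
  sc <- make_phantom_scene(rod_delta_mua = 0)
  img <- render_delta_od(sc$model, sc$view, sc$pulse, sc$gates[[1]],
                         n_photons = 2e5, seed = 4,
                         render_pixels = c(16, 11))
  expect_true(all(img$grid[!is.na(img$grid)] == 0))
})

test_that("direct two-run mode yields a positive contrast for a strong inclusion", {
  # shallow, strongly absorbing rod so the contrast dominates the noise
  # of the two independent runs
  model <- head_model(list(head_layer(Inf, 2.1, 0.04)),
                      inclusion_cylinder(10, c(0, 0, 18), axis = "z",
                                         length = 24, delta_mua = 0.5))
  view <- camera_view(c(40, 30), c(8, 6))
  img <- render_delta_od(model, view, pulse_shape(11), shutter_window(0, 11),
                         n_photons = 4e5, seed = 4, mode = "direct",
                         render_pixels = c(8, 6))
  ctr <- img$grid[3:4, 4:5]
  expect_true(all(is.finite(ctr)))
  expect_gt(mean(ctr), 0)
})

test_that("missing pixels are NA, not zero", {
  sc <- make_phantom_scene()
  # far too few photons to populate every native pixel
  img <- render_delta_od(sc$model, sc$view, sc$pulse, sc$gates[[3]],
                         n_photons = 2e4, seed = 4,
                         render_pixels = c(64, 44))
  expect_gt(sum(is.na(img$grid)), 0)
})

test_that("binning at the native pitch is the identity up to normalization", {
  set.seed(8)
  g <- matrix(runif(30 * 20), 20, 30)
  img <- delta_od_image(g, c(1, 1))
  out <- bin_resample(img, 1)
  expect_equal(out$grid, g / max(g), tolerance = 1e-9)
  cst <- delta_od_image(matrix(0.7, 20, 30), c(1, 1))
  expect_equal(bin_resample(cst, 5)$grid, matrix(1, 20, 30),
               tolerance = 1e-9)
  expect_error(bin_resample(img, 0.5), "native")
  expect_warning(bin_resample(img, 100), "field of view")
})

test_that("coarse binning broadens the rod blob and shifts its centroid", {
  im <- phantom_images()$smooth[[3]]
  base <- blob_metrics(normalize_image(im))
  b30 <- blob_metrics(bin_resample(im, 30))
  expect_gt(b30$fwhm_equiv, base$fwhm_equiv)
  shift <- sqrt(sum((b30$centroid_xy - base$centroid_xy)^2))
  expect_gt(shift, 0.5)
})

test_that("gaussian smoothing preserves the mean and reproduces its kernel", {
  set.seed(3)
  g <- matrix(rnorm(40 * 30, 5), 30, 40)
  img <- delta_od_image(g, c(1, 1))
  expect_equal(gaussian_smooth(img, 0)$grid, g)
  sm <- gaussian_smooth(img, 3)
  expect_equal(mean(sm$grid), mean(g), tolerance = 1e-6)
  # single impulse reproduces the separable kernel with unit sum
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  k <- dnorm(-8:8, sd = 2)
  k <- k / sum(k)
  sk <- gaussian_smooth(imp, 2)
  expect_equal(sum(sk), 1, tolerance = 1e-9)
  expect_equal(sk[13:29, 13:29], outer(k, k), tolerance = 1e-12)
  # NA pixels: normalized convolution keeps the result finite
  g2 <- g
  g2[5, 5] <- NA
  s2 <- gaussian_smooth(delta_od_image(g2, c(1, 1)), 2)
  expect_true(all(is.finite(s2$grid)))
})

test_that("blob metrics recover a synthetic Gaussian blob", {
  x <- seq_len(60)
  y <- seq_len(40)
  sigma <- 4
  g <- outer(exp(-(y - 18)^2 / (2 * sigma^2)),
             exp(-(x - 35)^2 / (2 * sigma^2)))
  img <- delta_od_image(g, c(1, 1), origin = c(1, 1))
  m <- blob_metrics(img)
  expect_equal(m$peak_xy, c(35, 18))
  expect_equal(m$centroid_xy, c(35, 18), tolerance = 0.05)
  # FWHM of a Gaussian is 2.355 sigma; the area-equivalent and the
  # profile measures agree with it at pixel resolution
  expect_equal(m$fwhm_x, 2.355 * sigma, tolerance = 0.15)
  expect_equal(m$fwhm_equiv, 2.355 * sigma, tolerance = 0.15)
})

test_that("rendered images persist as float TIFF with JSON sidecar", {
  im <- phantom_images()$smooth[[3]]
  tf <- tempfile(fileext = ".tiff")
  write_delta_od_tiff(im, tf, meta = list(gate_ns = 0.8),
                      png_preview = tempfile(fileext = ".png"))
  side <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(side$gate_ns, 0.8)
  stored <- tiff::readTIFF(tf)
  back <- (2 * stored - 1) * side$scale_max_abs
  g <- im$grid
  g[is.na(g)] <- 0
  expect_equal(back, g, tolerance = 1e-6)
})
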