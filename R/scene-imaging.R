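#' Camera view geometry
#'
#' @param fov field of view on the object, numeric length 2 (mm x mm).
#' @param pixels pixel count, numeric length 2 (cols x rows).
#' @param working_distance camera-to-surface distance (mm).
#' @return an object of class `camera_view`.
#' @export
camera_view <- function(fov = c(64, 44), pixels = c(320, 240),
                        working_distance = 150) {
  stopifnot(length(fov) == 2L, all(fov > 0), length(pixels) == 2L,
            all(pixels >= 1), working_distance > 0)
  structure(list(fov = as.numeric(fov), pixels = as.integer(pixels),
                 working_distance = as.numeric(working_distance)),
            class = "camera_view")
}

#' Construct a ΔOD image container
#'
#' @param grid numeric matrix of ΔOD values (-Δ ln I); rows run along y,
#'   columns along x.
#' @param pixel_pitch numeric length 2, pixel pitch (mm) in x and y.
#' @param origin surface coordinates (mm) of the centre of pixel
#'   `grid[1, 1]`.
#' @return an object of class `delta_od_image`.
#' @export
delta_od_image <- function(grid, pixel_pitch, origin = c(0, 0)) {
  stopifnot(is.matrix(grid), length(pixel_pitch) == 2L,
            all(pixel_pitch > 0), length(origin) == 2L)
  structure(list(grid = grid, pixel_pitch = as.numeric(pixel_pitch),
                 origin = as.numeric(origin)),
            class = "delta_od_image")
}

#' @export
print.delta_od_image <- function(x, ...) {
  rng <- range(x$grid, na.rm = TRUE)
  cat(sprintf(
    "DeltaOD image: %d x %d px, pitch %.3g x %.3g mm, range [%.3g, %.3g], %d missing\n",
    ncol(x$grid), nrow(x$grid), x$pixel_pitch[1], x$pixel_pitch[2],
    rng[1], rng[2], sum(is.na(x$grid))))
  invisible(x)
}

#' Pixel-centre coordinates of an image
#' @param image a `delta_od_image`.
#' @return list with numeric vectors `x` (per column) and `y` (per row).
#' @export
pixel_centers <- function(image) {
  list(x = image$origin[1] + (seq_len(ncol(image$grid)) - 1) *
         image$pixel_pitch[1],
       y = image$origin[2] + (seq_len(nrow(image$grid)) - 1) *
         image$pixel_pitch[2])
}

#' Render ΔOD images of a deep absorbing inclusion
#'
#' Simulates gated wide-field detection of the model's inclusion and forms
#' per-pixel ΔOD = -ln(I_active / I_rest) maps over the camera's field of
#' view, centred on the surface origin. The flat-top illumination covers
#' the whole field of view, so all pixels come from a single simulation
#' by binning exit positions.
#'
#' Two modes:
#' \describe{
#'   \item{perturbation}{one baseline run records each photon's path
#'     through the inclusion; the active image reweights photons by
#'     `exp(-delta_mua * path_inclusion)` (first-order accurate for
#'     `delta_mua * path << 1`, exact within the recorded-path model).}
#'   \item{direct}{two full runs with the same seed, with and without the
#'     inclusion's absorption applied along the walk.}
#' }
#'
#' @param model a [head_model()] with an inclusion (`delta_mua >= 0`).
#' @param view a [camera_view()].
#' @param pulse a [pulse_shape()] (square emission pulse).
#' @param window a [shutter_window()] or a list of them; a list returns a
#'   named list of images sharing the same simulation.
#' @param n_photons photons to launch.
#' @param seed integer seed.
#' @param mode `"perturbation"` (default) or `"direct"`.
#' @param render_pixels optional pixel count (cols x rows) overriding the
#'   view's native count, to trade resolution for per-pixel statistics.
#' @param chunk photons per simulator call; per-pixel sums are accumulated
#'   across chunks so large runs never hold a full tally in memory.
#' @return a `delta_od_image` (or named list of them). Pixels with no
#'   detected baseline weight are `NA` (missing, not zero).
#' @export
render_delta_od <- function(model, view, pulse, window, n_photons = 1e6,
                            seed = 1, mode = c("perturbation", "direct"),
                            render_pixels = NULL, chunk = 2e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "head_model"), inherits(view, "camera_view"))
  if (is.null(model$inclusion)) stop("model has no inclusion to render")
  windows <- if (inherits(window, "shutter_window")) list(window) else window
  stopifnot(all(vapply(windows, inherits, TRUE, "shutter_window")))
  px <- if (is.null(render_pixels)) view$pixels else as.integer(render_pixels)
  pitch <- view$fov / px
  src <- source_rect(view$fov[1], view$fov[2])
  det <- detector_rect(view$fov[1], view$fov[2])
  pw <- pulse$width
  dmua <- model$inclusion$delta_mua
  nw <- length(windows)
  rest <- act <- lapply(seq_len(nw), function(i) matrix(0, px[2], px[1]))
  model_rest <- head_model(model$layers) # inclusion absent entirely

  accumulate <- function(tally, which, gate_i, mats) {
    ph <- tally$photons
    ix <- pmin(pmax(floor((ph$exit_x + view$fov[1] / 2) / pitch[1]), 0),
               px[1] - 1L) + 1L
    iy <- pmin(pmax(floor((ph$exit_y + view$fov[2] / 2) / pitch[2]), 0),
               px[2] - 1L) + 1L
    cell <- (ix - 1L) * px[2] + iy
    g <- square_gate_weight(ph$exit_time, windows[[gate_i]]$open_delay,
                            windows[[gate_i]]$width, pw, impulse_width = 1)
    w <- ph$weight * g
    if (which == "act_pert") w <- w * exp(-dmua * ph$path_inclusion)
    keep <- w > 0
    s <- tapply(w[keep], cell[keep], sum)
    mats[as.integer(names(s))] <- mats[as.integer(names(s))] + as.numeric(s)
    mats
  }

  n_left <- n_photons
  chunk_seed <- seed
  while (n_left > 0) {
    n_run <- min(chunk, n_left)
    if (mode == "perturbation") {
      tl <- mc_simulate(model, src, det, n_photons = n_run,
                        seed = chunk_seed, apply_inclusion = FALSE,
                        keep_layer_paths = FALSE)
      for (i in seq_len(nw)) {
        rest[[i]] <- accumulate(tl, "rest", i, rest[[i]])
        act[[i]] <- accumulate(tl, "act_pert", i, act[[i]])
      }
    } else {
      tl0 <- mc_simulate(model_rest, src, det, n_photons = n_run,
                         seed = chunk_seed, keep_layer_paths = FALSE)
      tl1 <- mc_simulate(model, src, det, n_photons = n_run,
                         seed = chunk_seed, apply_inclusion = TRUE,
                         keep_layer_paths = FALSE)
      for (i in seq_len(nw)) {
        rest[[i]] <- accumulate(tl0, "rest", i, rest[[i]])
        act[[i]] <- accumulate(tl1, "act", i, act[[i]])
      }
    }
    n_left <- n_left - n_run
    chunk_seed <- chunk_seed + 1L
  }

  origin <- c(-view$fov[1] / 2 + pitch[1] / 2, -view$fov[2] / 2 + pitch[2] / 2)
  images <- lapply(seq_len(nw), function(i) {
    g <- -log(act[[i]] / rest[[i]])
    g[!is.finite(g) | rest[[i]] <= 0] <- NA_real_
    delta_od_image(g, pitch, origin)
  })
  names(images) <- vapply(windows, function(w)
    sprintf("gate_%gns", w$open_delay), "")
  if (inherits(window, "shutter_window")) images[[1]] else images
}

# Keys cubic-convolution kernel, a = -0.5
.cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# 1-D cubic interpolation of values v (uniform grid, index coordinates)
# at positions u (same coordinates); edges replicate.
.cubic_interp1 <- function(v, u) {
  n <- length(v)
  if (n == 1L) return(rep(v, length(u)))
  i0 <- floor(u)
  out <- numeric(length(u))
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 1L), n)
    out <- out + v[idx] * .cubic_kernel(u - (i0 + k))
  }
  out
}

#' Bin an image to a coarse sampling pitch and interpolate back
#'
#' Emulates a sparse probe-grid measurement: block-averages the image at
#' the stated pitch (partial edge blocks average over their available
#' pixels), then bicubically interpolates back to the original pixel
#' count, and finally normalizes the result by its own maximum.
#'
#' @param image a `delta_od_image`.
#' @param pitch sampling pitch in mm (>= the native pixel pitch).
#' @return a `delta_od_image` at the original resolution, unit maximum.
#' @export
bin_resample <- function(image, pitch) {
  stopifnot(inherits(image, "delta_od_image"), pitch > 0)
  if (pitch < max(image$pixel_pitch))
    stop("pitch must be at least the native pixel pitch")
  g <- image$grid
  bs <- pitch / image$pixel_pitch # block size in pixels (x, y)
  nbx <- ceiling(ncol(g) / bs[1])
  nby <- ceiling(nrow(g) / bs[2])
  if (nbx <= 1 && nby <= 1)
    warning("pitch is larger than the field of view; single-block output")
  bx <- pmin(ceiling(seq_len(ncol(g)) / bs[1]), nbx)
  by <- pmin(ceiling(seq_len(nrow(g)) / bs[2]), nby)
  blocks <- matrix(NA_real_, nby, nbx)
  for (j in seq_len(nbx))
    for (i in seq_len(nby))
      blocks[i, j] <- mean(g[by == i, bx == j, drop = FALSE], na.rm = TRUE)
  # interpolate block values back to pixel centres (block-index coords)
  ux <- (seq_len(ncol(g)) - 0.5) / bs[1] + 0.5
  uy <- (seq_len(nrow(g)) - 0.5) / bs[2] + 0.5
  tmp <- t(apply(blocks, 1, .cubic_interp1, u = ux))     # nby x W
  if (nbx == 1L) tmp <- matrix(blocks[, 1], nby, ncol(g))
  out <- apply(tmp, 2, .cubic_interp1, u = uy)           # H x W
  out <- matrix(out, nrow(g), ncol(g))
  m <- max(out, na.rm = TRUE)
  if (m != 0) out <- out / m
  delta_od_image(out, image$pixel_pitch, image$origin)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with reflective boundary handling, which
#' preserves the image mean. `NA` pixels are handled by normalized
#' convolution (weights renormalized over available pixels).
#'
#' @param image a `delta_od_image` or plain matrix.
#' @param sigma_px kernel standard deviation in pixels (0 = identity).
#' @return same class as the input.
#' @export
gaussian_smooth <- function(image, sigma_px) {
  stopifnot(sigma_px >= 0)
  g <- if (inherits(image, "delta_od_image")) image$grid else image
  if (sigma_px > 0) {
    r <- max(1L, ceiling(4 * sigma_px))
    k <- stats::dnorm(seq(-r, r), sd = sigma_px)
    k <- k / sum(k)
    smooth1 <- function(m) { # convolve columns of m with k, reflective
      n <- nrow(m)
      idx <- c(rev(seq_len(min(r, n))), seq_len(n),
               rev(seq_len(n))[seq_len(min(r, n))])
      if (r > n) { # pathological small images: clamp padding
        idx <- c(rep(1L, r - n), idx, rep(n, r - n))
      }
      pad <- m[idx, , drop = FALSE]
      out <- matrix(0, n, ncol(m))
      wsum <- matrix(0, n, ncol(m))
      na_mask <- is.na(pad)
      pad[na_mask] <- 0
      for (j in seq_along(k)) {
        rows <- seq_len(n) + (j - 1L)
        out <- out + k[j] * pad[rows, , drop = FALSE]
        wsum <- wsum + k[j] * !na_mask[rows, , drop = FALSE]
      }
      res <- out / wsum
      res[wsum == 0] <- NA_real_
      res
    }
    g <- t(smooth1(t(smooth1(g))))
  }
  if (inherits(image, "delta_od_image")) {
    image$grid <- g
    image
  } else g
}

#' Normalize an image by its maximum
#'
#' @param image a `delta_od_image`.
#' @param reference optional second image whose maximum is used instead
#'   (e.g. normalizing a gate series by the latest gate).
#' @return a `delta_od_image` with unit maximum.
#' @export
normalize_image <- function(image, reference = NULL) {
  m <- max((reference %||% image)$grid, na.rm = TRUE)
  if (m == 0) stop("cannot normalize: image maximum is zero")
  image$grid <- image$grid / m
  image
}

#' Blob metrics of a ΔOD image
#'
#' Summarizes the dominant positive blob: peak value and position, the
#' intensity-weighted centroid over the at-least-half-maximum region, the
#' area-equivalent full width at half maximum, and the per-axis FWHM of
#' the profiles through the peak.
#'
#' @param image a `delta_od_image`.
#' @return a list with `peak`, `peak_xy` (mm), `centroid_xy` (mm),
#'   `fwhm_equiv` (mm), `fwhm_x`, `fwhm_y` (mm), `area_mm2`.
#' @export
blob_metrics <- function(image) {
  g <- image$grid
  cc <- pixel_centers(image)
  pk <- max(g, na.rm = TRUE)
  at <- which(g == pk, arr.ind = TRUE)[1, ]
  half <- !is.na(g) & g >= pk / 2
  px_area <- prod(image$pixel_pitch)
  area <- sum(half) * px_area
  wgt <- ifelse(half, g, 0)
  wgt[is.na(wgt)] <- 0
  cx <- sum(outer(rep(1, nrow(g)), cc$x) * wgt) / sum(wgt)
  cy <- sum(outer(cc$y, rep(1, ncol(g))) * wgt) / sum(wgt)
  fw <- function(prof, coords) {
    ok <- which(!is.na(prof) & prof >= pk / 2)
    if (length(ok) == 0) return(0)
    diff(range(coords[ok])) + mean(diff(coords))
  }
  list(peak = pk, peak_xy = c(cc$x[at[2]], cc$y[at[1]]),
       centroid_xy = c(cx, cy), fwhm_equiv = 2 * sqrt(area / pi),
       fwhm_x = fw(g[at[1], ], cc$x), fwhm_y = fw(g[, at[2]], cc$y),
       area_mm2 = area)
}

#' Write a ΔOD image as 32-bit float TIFF with a JSON sidecar
#'
#' The TIFF stores the image scaled to \[0, 1\]; the sidecar records the
#' scale factor, pixel pitch, origin and any metadata passed in `meta`.
#' An optional 8-bit PNG preview uses the same linear grey scale.
#'
#' @param image a `delta_od_image`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param meta named list merged into the sidecar (e.g. gate timing, seed).
#' @param png_preview optional PNG path.
#' @return `path`, invisibly.
#' @export
write_delta_od_tiff <- function(image, path, meta = list(),
                                png_preview = NULL) {
  g <- image$grid
  g[is.na(g)] <- 0
  m <- max(abs(g))
  scaled <- if (m > 0) (g / m + 1) / 2 else g * 0 + 0.5
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  side <- c(list(scale_max_abs = m, encoding = "value = (2*stored - 1) * scale_max_abs",
                 pixel_pitch_mm = image$pixel_pitch, origin_mm = image$origin,
                 missing_encoded_as = 0), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(png_preview)) png::writePNG(scaled, png_preview)
  invisible(path)
}
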