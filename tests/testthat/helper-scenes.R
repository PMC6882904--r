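# Shared fixtures and independent oracles, built in code at test time.

# Independently coded, unvectorized reference random walk for a single
# homogeneous semi-infinite medium: isotropic scattering at rate mus,
# continuous absorption weight exp(-mua * l), exit on any upward surface
# crossing, path capped at max_path. Returns total diffuse reflectance
# per launched photon with its Monte Carlo standard error.
oracle_reflectance <- function(n, mus, mua, max_path = 1000, seed = 1) {
  set.seed(seed)
  tot <- 0
  tot2 <- 0
  for (i in seq_len(n)) {
    z <- 0
    ux <- 0; uy <- 0; uz <- 1
    w <- 1
    path <- 0
    repeat {
      s <- -log(runif(1)) / mus
      if (uz < 0 && z + uz * s < 0) {
        d <- -z / uz
        w <- w * exp(-mua * d)
        tot <- tot + w
        tot2 <- tot2 + w * w
        break
      }
      w <- w * exp(-mua * s)
      path <- path + s
      if (path > max_path) break
      z <- z + uz * s
      uz <- 2 * runif(1) - 1
      phi <- 2 * pi * runif(1)
      st <- sqrt(1 - uz * uz)
      ux <- st * cos(phi)
      uy <- st * sin(phi)
    }
  }
  m <- tot / n
  list(R = m, se = sqrt(max(tot2 / n - m * m, 0) / n))
}

# standard error of the engine's detected-weight fraction
tally_detected_se <- function(tally) {
  w <- tally$photons$weight
  N <- tally$totals$launched
  sqrt(max(sum(w^2) - sum(w)^2 / N, 0)) / N
}

# small homogeneous semi-infinite model matching the oracle's physics
homog_model <- function(mua = 0.04, mus = 2.1)
  head_model(head_layer(Inf, mus, mua))

full_surface <- function() detector_rect(1e6, 1e6)

point_source <- function() source_rect(1e-6, 1e-6)

# lazy cache for expensive shared simulations (one per test session)
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Table-1 impulse tally with the 10 x 10 mm detector and brain 0-4 mm slab
table1_tally <- function(n = 2e6) {
  cached("table1", {
    sc <- make_phantom_scene()
    mc_simulate(sc$model_rest, sc$source, sc$detector_10mm, slab = sc$slab,
                n_photons = n, seed = 42, keep_layer_paths = FALSE)
  })
}

# rendered three-gate phantom images (smoothed), shared by image tests
phantom_images <- function(n = 2e6) {
  cached("phantom_imgs", {
    sc <- make_phantom_scene()
    sigma <- 18 * 64 / 320 # phantom smoothing rescaled to the render grid
    imgs <- render_delta_od(sc$model, sc$view, sc$pulse, sc$gates,
                            n_photons = n, seed = 42,
                            render_pixels = c(64, 44))
    list(raw = imgs,
         smooth = lapply(imgs, gaussian_smooth, sigma_px = sigma),
         sigma_px = sigma, sigma_mm = sigma * 1)
  })
}
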