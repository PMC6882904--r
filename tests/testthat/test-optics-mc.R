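test_that("energy is conserved exactly and fully recovered without absorption", {
  m <- homog_model(mua = 0)
  tl <- mc_simulate(m, point_source(), full_surface(), n_photons = 1e4,
                    seed = 1, max_path = 2000)
  tt <- tl$totals
  expect_equal(tt$absorbed, 0)
  # everything launched is either detected or path-capped
  expect_lt(weight_balance_error(tl), 1e-12)
  expect_equal(tt$detected + tt$capped, tt$launched, tolerance = 1e-12)
  expect_gt(tt$detected / tt$launched, 0.95)
  expect_equal(nrow(tl$photons), as.integer(tt$n_detected))
})

test_that("weight balance closes through absorption, roulette and transmission", {
  tl <- table1_tally()
  expect_lt(weight_balance_error(tl), 1e-6)
  # finite bottom layer: transmitted weight appears in the escaped tally
  thin <- head_model(head_layer(5, 2, 0))
  tr <- mc_simulate(thin, point_source(), detector_rect(1e-7, 1e-7),
                    n_photons = 5e3, seed = 2, max_path = 2000)
  expect_lt(weight_balance_error(tr), 1e-12)
  expect_gt(tr$totals$escaped, 0)
})

test_that("per-photon layer partial paths sum to the total path", {
  sc <- make_phantom_scene()
  tl <- mc_simulate(sc$model_rest, sc$source, sc$detector_10mm,
                    n_photons = 2e4, seed = 3)
  expect_false(is.null(tl$path_layers))
  expect_equal(rowSums(tl$path_layers), tl$photons$path_total,
               tolerance = 1e-10)
  expect_true(all(tl$photons$path_total >= 0))
  expect_true(all(tl$path_layers >= 0))
  # exit time equals the per-layer time sum (uniform n = 1.4 here)
  expect_equal(tl$photons$exit_time,
               tl$photons$path_total * 1.4 / 299.792458, tolerance = 1e-10)
})

test_that("identical inputs and seed reproduce the tally exactly", {
  m <- homog_model()
  a <- mc_simulate(m, source_rect(2, 2), full_surface(), n_photons = 5e3,
                   seed = 7)
  b <- mc_simulate(m, source_rect(2, 2), full_surface(), n_photons = 5e3,
                   seed = 7)
  expect_identical(a$photons, b$photons)
  expect_identical(a$totals, b$totals)
  c <- mc_simulate(m, source_rect(2, 2), full_surface(), n_photons = 5e3,
                   seed = 8)
  expect_false(identical(a$photons, c$photons))
})

test_that("detected weight is non-increasing in any layer's absorption", {
  # thin superficial layer over a semi-infinite lower layer so that both
  # layers contribute materially to the detected weight
  base <- list(head_layer(2, 1.8, 0.019), head_layer(Inf, 2.1, 0.04))
  frac <- function(layers) {
    tl <- mc_simulate(head_model(layers), source_rect(10, 10),
                      detector_rect(60, 60), n_photons = 3e4, seed = 11,
                      keep_layer_paths = FALSE)
    tl$totals$detected / tl$totals$launched
  }
  f0 <- frac(base)
  more_top <- base
  more_top[[1]] <- head_layer(2, 1.8, 0.19)
  more_deep <- base
  more_deep[[2]] <- head_layer(Inf, 2.1, 0.4)
  expect_lt(frac(more_top), f0)
  expect_lt(frac(more_deep), f0)
})

test_that("engine reflectance matches an independent scalar random walk", {
  n_engine <- 4e4
  n_oracle <- 8e3
  tl <- mc_simulate(homog_model(0.04, 2.1), point_source(), full_surface(),
                    n_photons = n_engine, seed = 5, max_path = 1000,
                    keep_layer_paths = FALSE)
  engine_R <- tl$totals$detected / tl$totals$launched
  engine_se <- tally_detected_se(tl)
  orc <- oracle_reflectance(n_oracle, mus = 2.1, mua = 0.04,
                            max_path = 1000, seed = 6)
  expect_lt(abs(engine_R - orc$R),
            3 * sqrt(engine_se^2 + orc$se^2))
})

test_that("inclusion reweighting equals directly applied absorption", {
  # with roulette disabled the two modes share identical trajectories,
  # so the first-order reweighting must reproduce the direct run exactly
  sc <- make_phantom_scene()
  src <- source_rect(40, 40)
  det <- detector_rect(30, 30)
  base <- mc_simulate(sc$model, src, det, n_photons = 5e4, seed = 13,
                      w_min = 0, keep_layer_paths = FALSE)
  direct <- mc_simulate(sc$model, src, det, n_photons = 5e4, seed = 13,
                        w_min = 0, apply_inclusion = TRUE,
                        keep_layer_paths = FALSE)
  expect_equal(direct$photons$weight,
               base$photons$weight *
                 exp(-sc$model$inclusion$delta_mua *
                       base$photons$path_inclusion),
               tolerance = 1e-12)
  expect_gt(max(base$photons$path_inclusion), 0)
  # independent-seed statistical agreement of the gated intensities
  other <- mc_simulate(sc$model, src, det, n_photons = 2e5, seed = 14,
                       apply_inclusion = TRUE, keep_layer_paths = FALSE)
  base2 <- mc_simulate(sc$model, src, det, n_photons = 2e5, seed = 15,
                       keep_layer_paths = FALSE)
  gate <- function(t) square_gate_weight(t$photons$exit_time, 0.4, 11, 11, 1)
  se_sum <- function(x, N) sqrt(max(sum(x^2) - sum(x)^2 / N, 0))
  x_dir <- other$photons$weight * gate(other)
  x_pert <- base2$photons$weight * gate(base2) *
    exp(-0.01 * base2$photons$path_inclusion)
  N <- 2e5
  expect_lt(abs(sum(x_dir) - sum(x_pert)),
            3 * sqrt(se_sum(x_dir, N)^2 + se_sum(x_pert, N)^2))
})

test_that("mean partial path per time bin behaves at the limits", {
  # slab spanning the whole (finite) medium: slab path equals total path
  m <- head_model(head_layer(50, 2, 0.02))
  tl <- mc_simulate(m, point_source(), full_surface(),
                    slab = depth_slab(1, 0, 50), n_photons = 1e4, seed = 9)
  expect_equal(tl$photons$path_slab, tl$photons$path_total,
               tolerance = 1e-10)
  br <- seq(0, 1, by = 0.1)
  cs <- mean_partial_path_vs_time(tl, br, path = "slab")
  ct <- mean_partial_path_vs_time(tl, br, path = "total")
  expect_equal(cs$mean_path, ct$mean_path)
  # slab deeper than the path cap can reach: all means exactly zero
  m2 <- homog_model()
  tl2 <- mc_simulate(m2, point_source(), full_surface(),
                     slab = depth_slab(1, 150, 180), n_photons = 5e3,
                     seed = 10, max_path = 200)
  c2 <- mean_partial_path_vs_time(tl2, seq(0, 2, by = 0.5))
  expect_true(all(c2$mean_path[!c2$empty] == 0))
  # empty bins are flagged NA, not zero
  c3 <- mean_partial_path_vs_time(tl, c(100, 200, 300))
  expect_true(all(c3$empty))
  expect_true(all(is.na(c3$mean_path)))
  # error paths
  expect_error(mean_partial_path_vs_time(tl, c(1, 1, 2)),
               "strictly increasing")
  empty_tally <- mc_simulate(m2, point_source(),
                             detector_rect(1e-9, 1e-9, center = c(500, 500)),
                             n_photons = 10, seed = 1)
  expect_error(mean_partial_path_vs_time(empty_tally, br),
               "no detected photons")
})

test_that("later-arriving detected light carries longer brain-slab paths", {
  # the published configuration: 1 x 1 mm detector centred in the
  # 64 x 18 mm illuminated region of the layered head model
  sc <- make_phantom_scene()
  tl <- mc_simulate(sc$model_rest, sc$source, sc$detector_1mm,
                    slab = sc$slab, n_photons = 1e6, seed = 21,
                    keep_layer_paths = FALSE)
  # a 1 mm^2 detector is photon-starved at desk scale: two wide bins
  cv <- mean_partial_path_vs_time(tl, c(0, 0.3, 1.2))
  expect_true(all(cv$n >= 10))
  expect_true(all(diff(cv$mean_path) > 0))
})

test_that("tallies export as flat CSV with documented columns", {
  tl <- mc_simulate(homog_model(), source_rect(1, 1), full_surface(),
                    n_photons = 1e3, seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_tally_csv(tl, tf)
  back <- read.csv(tf)
  expect_true(all(c("exit_time", "exit_x", "exit_y", "weight", "path_total",
                    "path_slab", "path_inclusion", "path_layer1") %in%
                    names(back)))
  expect_equal(nrow(back), nrow(tl$photons))
  expect_equal(back$weight, tl$photons$weight, tolerance = 1e-12)
})
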