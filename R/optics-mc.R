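#' Speed of light in vacuum, mm/ns
#' @keywords internal
.c_mm_ns <- 299.792458

#' Time-resolved Monte Carlo photon transport
#'
#' Simulates weighted photon random walks in a layered semi-infinite medium
#' and tallies every photon whose upward surface crossing falls inside the
#' detector footprint: exit time (origin = photon entry), exit position,
#' survival weight, per-layer partial path lengths, the partial path inside
#' an optional depth slab, and the partial path inside the model's
#' inclusion (0 if none).
#'
#' Physics: isotropic scattering at rate mu_s' (similarity relation),
#' continuous weight attenuation `exp(-mua * l)` per segment, index-matched
#' boundaries, per-layer speed c/n for the time of flight, Russian roulette
#' below weight 1e-4 (survival probability 0.1), and a total path-length
#' cap that terminates pathological trajectories. The realised roulette
#' weight change is tallied, so the energy balance
#' launched = detected + escaped + absorbed + capped + roulette_net
#' closes to floating-point rounding.
#'
#' @param model a [head_model()].
#' @param source a [source_rect()].
#' @param detector a [detector_rect()].
#' @param slab optional [depth_slab()] for the slab partial-path tally.
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer seed; identical inputs and seed give identical
#'   tallies.
#' @param apply_inclusion if `TRUE`, the inclusion's `delta_mua` is applied
#'   as true absorption along the walk ("direct" mode); if `FALSE`
#'   (default) trajectories see only the layer absorption and the
#'   inclusion path is merely recorded, so absorption perturbations can be
#'   applied afterwards by reweighting `exp(-delta_mua * path_inclusion)`.
#' @param max_path total path-length cap in mm (default 5000).
#' @param keep_layer_paths keep the per-photon, per-layer path matrix
#'   (default `TRUE`; disable to halve memory on large wide-field runs).
#' @param w_min,rr_p Russian-roulette threshold and survival probability.
#' @return an object of class `photon_tally`: list with `photons` (a
#'   data.frame with columns `exit_time` (ns), `exit_x`, `exit_y` (mm),
#'   `weight`, `path_total`, `path_slab`, `path_inclusion` (mm)),
#'   `path_layers` (matrix, detected photons x layers, or `NULL`),
#'   `totals` (launched/detected/escaped/absorbed/capped/roulette_net
#'   weights and `n_detected`), and the simulation metadata.
#' @export
mc_simulate <- function(model, source, detector, slab = NULL,
                        n_photons = 1e5, seed = 1,
                        apply_inclusion = FALSE, max_path = 5000,
                        keep_layer_paths = TRUE,
                        w_min = 1e-4, rr_p = 0.1) {
  stopifnot(inherits(model, "head_model"), inherits(source, "source_rect"),
            inherits(detector, "detector_rect"), n_photons >= 1)
  lt <- layer_table(model)
  slab_abs <- c(0, 0)
  if (!is.null(slab)) {
    stopifnot(inherits(slab, "depth_slab"))
    slab_abs <- slab_absolute(model, slab)
  }
  inc <- model$inclusion
  has_incl <- !is.null(inc)
  axis_i <- if (has_incl) match(inc$axis, c("x", "y", "z")) - 1L else 2L
  set.seed(seed)
  raw <- .mc_transport_cpp(
    lt$thickness, lt$mus_prime, lt$mua, lt$refractive_index,
    rect_bounds(source), rect_bounds(detector),
    !is.null(slab), slab_abs[1], slab_abs[2],
    has_incl, axis_i,
    if (has_incl) inc$center[1] else 0,
    if (has_incl) inc$center[2] else 0,
    if (has_incl) inc$center[3] else 0,
    if (has_incl) inc$diameter / 2 else 0,
    if (has_incl) inc$length / 2 else Inf,
    if (has_incl) inc$delta_mua else 0,
    has_incl && apply_inclusion,
    as.numeric(n_photons), max_path, w_min, rr_p,
    keep_layer_paths, .c_mm_ns)
  photons <- data.frame(exit_time = raw$exit_time, exit_x = raw$exit_x,
                        exit_y = raw$exit_y, weight = raw$weight,
                        path_total = raw$path_total,
                        path_slab = raw$path_slab,
                        path_inclusion = raw$path_inclusion)
  pl <- raw$path_layers
  if (!is.null(pl)) {
    pl <- t(pl)
    colnames(pl) <- paste0("path_layer", seq_len(ncol(pl)))
  }
  structure(list(photons = photons, path_layers = pl,
                 totals = raw$totals,
                 model = model, source = source, detector = detector,
                 slab = slab, n_photons = n_photons, seed = seed,
                 apply_inclusion = apply_inclusion, max_path = max_path,
                 time_origin = "photon_entry"),
            class = "photon_tally")
}

#' @export
print.photon_tally <- function(x, ...) {
  tt <- x$totals
  cat(sprintf(
    "Photon tally: %d detected / %g launched (detected weight %.4g)\n",
    as.integer(tt$n_detected), tt$launched, tt$detected))
  cat(sprintf("  escaped %.4g, absorbed %.4g, capped %.4g, roulette %.3g\n",
              tt$escaped, tt$absorbed, tt$capped, tt$roulette_net))
  invisible(x)
}

#' @export
as.data.frame.photon_tally <- function(x, ...) {
  if (is.null(x$path_layers)) x$photons
  else cbind(x$photons, as.data.frame(x$path_layers))
}

#' Export a photon tally as a flat CSV table
#'
#' Columns: `exit_time` (ns since photon entry), `exit_x`, `exit_y` (mm),
#' `weight`, `path_total`, `path_slab`, `path_inclusion` and, when kept,
#' `path_layer<k>` (all mm).
#'
#' @param tally a `photon_tally`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  utils::write.csv(as.data.frame(tally), path, row.names = FALSE)
  invisible(path)
}

#' Weight-balance check of a tally
#'
#' @param tally a `photon_tally`.
#' @return relative imbalance |launched - (detected + escaped + absorbed +
#'   capped + roulette_net)| / launched.
#' @export
weight_balance_error <- function(tally) {
  tt <- tally$totals
  abs(tt$launched - (tt$detected + tt$escaped + tt$absorbed + tt$capped +
                       tt$roulette_net)) / tt$launched
}

#' Mean partial path length versus arrival time
#'
#' Bins detected photons by arrival time and reports the weighted mean of
#' a partial path length per bin: `sum(w * L) / sum(w)` over photons in the
#' bin. Bins containing no photons are flagged empty (`NA`), not zero.
#'
#' @param tally a non-empty `photon_tally`.
#' @param breaks strictly increasing time-bin edges (ns, same origin as
#'   the tally, i.e. photon entry).
#' @param path which partial path to average: `"slab"` (default),
#'   `"inclusion"` or `"total"`.
#' @param weights optional per-photon weights overriding the tally
#'   survival weights (e.g. gated weights for a square-pulse input).
#' @return a data.frame with columns `t_lo`, `t_hi`, `t_mid` (ns),
#'   `mean_path` (mm, `NA` for empty bins), `se` (weighted standard error),
#'   `n` (photon count), `weight` (summed weight), `empty` (logical).
#' @export
mean_partial_path_vs_time <- function(tally, breaks, path = "slab",
                                      weights = NULL) {
  stopifnot(inherits(tally, "photon_tally"))
  ph <- tally$photons
  if (nrow(ph) == 0L) stop("tally contains no detected photons")
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  path <- match.arg(path, c("slab", "inclusion", "total"))
  L <- switch(path, slab = ph$path_slab, inclusion = ph$path_inclusion,
              total = ph$path_total)
  w <- if (is.null(weights)) ph$weight else weights
  idx <- findInterval(ph$exit_time, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  out <- data.frame(t_lo = breaks[-length(breaks)], t_hi = breaks[-1])
  out$t_mid <- (out$t_lo + out$t_hi) / 2
  out$mean_path <- out$se <- rep(NA_real_, nb)
  out$n <- out$weight <- rep(0, nb)
  for (b in seq_len(nb)) {
    in_b <- which(idx == b & w > 0)
    out$n[b] <- length(in_b)
    if (length(in_b) == 0L) next
    wb <- w[in_b]
    lb <- L[in_b]
    sw <- sum(wb)
    m <- sum(wb * lb) / sw
    out$weight[b] <- sw
    out$mean_path[b] <- m
    # effective-sample-size weighted SE
    neff <- sw^2 / sum(wb^2)
    if (neff > 1) {
      s2 <- sum(wb * (lb - m)^2) / sw * neff / (neff - 1)
      out$se[b] <- sqrt(s2 / neff)
    }
  }
  out$empty <- out$n == 0L
  out
}

#' Write a two-column curve as CSV
#'
#' @param curve a data.frame whose first two retained columns are x and y
#'   (e.g. output of [mean_partial_path_vs_time()] using `t_mid` and
#'   `mean_path`).
#' @param path output file.
#' @param x,y column names to write.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, x = "t_mid", y = "mean_path") {
  utils::write.csv(curve[, c(x, y)], path, row.names = FALSE)
  invisible(path)
}
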