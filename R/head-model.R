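#' Tissue layer specification
#'
#' One horizontal layer of the layered head model. Only the transport
#' (reduced) scattering coefficient is used: scattering is isotropic with
#' step rate `mus_prime` under the similarity relation, so no anisotropy
#' parameter is needed.
#'
#' @param thickness layer thickness in mm; `Inf` for a semi-infinite
#'   bottom layer (only the last layer of a model may be unbounded).
#' @param mus_prime transport scattering coefficient in mm^-1.
#' @param mua absorption coefficient in mm^-1.
#' @param refractive_index dimensionless; enters only through the photon
#'   speed c/n (boundaries are index-matched).
#' @param name optional layer label.
#' @return an object of class `head_layer`.
#' @export
head_layer <- function(thickness, mus_prime, mua, refractive_index = 1.4,
                       name = NULL) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L, thickness > 0,
            is.numeric(mus_prime), mus_prime >= 0,
            is.numeric(mua), mua >= 0,
            is.numeric(refractive_index), refractive_index > 0)
  structure(list(thickness = as.numeric(thickness),
                 mus_prime = as.numeric(mus_prime),
                 mua = as.numeric(mua),
                 refractive_index = as.numeric(refractive_index),
                 name = name),
            class = "head_layer")
}

#' Embedded absorbing cylinder
#'
#' An axis-aligned cylindrical perturbation ("activation rod") embedded in
#' the layered medium. Its scattering equals the background; only the
#' absorption change `delta_mua` distinguishes it.
#'
#' @param diameter cylinder diameter in mm.
#' @param center numeric length-3, centre (x, y, z) in mm; z is depth below
#'   the surface.
#' @param axis one of "x", "y", "z" — the cylinder axis direction.
#' @param length axial length in mm; `Inf` for an effectively unbounded rod.
#' @param delta_mua absorption change inside the rod, mm^-1 (may be 0).
#' @return an object of class `inclusion_cylinder`.
#' @export
inclusion_cylinder <- function(diameter, center, axis = "z", length = Inf,
                               delta_mua = 0) {
  axis <- match.arg(axis, c("x", "y", "z"))
  stopifnot(diameter > 0, length(center) == 3L, length > 0, delta_mua >= 0)
  structure(list(diameter = as.numeric(diameter),
                 center = as.numeric(center), axis = axis,
                 length = as.numeric(length),
                 delta_mua = as.numeric(delta_mua)),
            class = "inclusion_cylinder")
}

#' Layered head model
#'
#' Ordered list of [head_layer()]s from the top surface downward, with an
#' optional embedded [inclusion_cylinder()]. Coordinates are right-handed
#' with z increasing downward from the surface at z = 0; lengths in mm.
#'
#' @param layers a list of [head_layer()] objects (or a single layer).
#' @param inclusion optional [inclusion_cylinder()]; must lie entirely
#'   below the surface.
#' @return an object of class `head_model`.
#' @export
head_model <- function(layers, inclusion = NULL) {
  if (inherits(layers, "head_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "head_layer")))
  th <- vapply(layers, `[[`, 0, "thickness")
  if (any(!is.finite(th[-length(th)])))
    stop("only the last layer may be semi-infinite")
  if (!is.null(inclusion)) {
    stopifnot(inherits(inclusion, "inclusion_cylinder"))
    r <- inclusion$diameter / 2
    zmin <- inclusion$center[3] -
      if (inclusion$axis == "z") min(inclusion$length / 2, 1e6) else r
    if (zmin < 0) stop("inclusion must lie entirely below the surface")
  }
  structure(list(layers = layers, inclusion = inclusion),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("Layered head model (", length(x$layers), " layers)\n", sep = "")
  df <- layer_table(x)
  print(df, row.names = FALSE)
  if (!is.null(x$inclusion)) {
    inc <- x$inclusion
    cat(sprintf(
      "Inclusion: %s-axis cylinder, diameter %g mm at (%g, %g, %g) mm, delta_mua %g mm^-1\n",
      inc$axis, inc$diameter, inc$center[1], inc$center[2], inc$center[3],
      inc$delta_mua))
  }
  invisible(x)
}

#' Layer table of a head model
#'
#' @param model a [head_model()].
#' @return a data.frame with one row per layer: name, thickness (mm),
#'   mus_prime (mm^-1), mua (mm^-1), refractive_index.
#' @export
layer_table <- function(model) {
  stopifnot(inherits(model, "head_model"))
  data.frame(
    name = vapply(model$layers, function(l) l$name %||% "", ""),
    thickness = vapply(model$layers, `[[`, 0, "thickness"),
    mus_prime = vapply(model$layers, `[[`, 0, "mus_prime"),
    mua = vapply(model$layers, `[[`, 0, "mua"),
    refractive_index = vapply(model$layers, `[[`, 0, "refractive_index"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rectangular surface source
#'
#' Flat-top illuminated rectangle on the top surface; photons launch at
#' uniformly random positions within it at normal incidence.
#'
#' @param width,height extent in x and y (mm).
#' @param center centre (x, y) on the surface, mm.
#' @param wavelength nominal wavelength in nm (metadata only).
#' @return an object of class `source_rect`.
#' @export
source_rect <- function(width, height, center = c(0, 0), wavelength = 855) {
  stopifnot(width > 0, height > 0, length(center) == 2L)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 center = as.numeric(center),
                 wavelength = as.numeric(wavelength)),
            class = "source_rect")
}

#' Rectangular surface detector
#'
#' Any upward surface crossing inside the footprint is tallied, regardless
#' of exit angle; angular acceptance into a lens is applied separately by
#' the solid-angle factor of the photon budget.
#'
#' @param width,height footprint extent in x and y (mm).
#' @param center centre (x, y) on the surface, mm.
#' @return an object of class `detector_rect`.
#' @export
detector_rect <- function(width, height, center = c(0, 0)) {
  stopifnot(width > 0, height > 0, length(center) == 2L)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 center = as.numeric(center)),
            class = "detector_rect")
}

rect_bounds <- function(r) {
  c(r$center[1] - r$width / 2, r$center[1] + r$width / 2,
    r$center[2] - r$height / 2, r$center[2] + r$height / 2)
}

rect_area <- function(r) r$width * r$height

#' Depth slab within a layer
#'
#' A horizontal slab used for partial-pathlength tallies, specified
#' relative to the top face of one layer (e.g. the first 4 mm of the brain
#' layer).
#'
#' @param layer 1-based layer index.
#' @param z_from,z_to slab range in mm relative to the layer's top face;
#'   `0 <= z_from < z_to <= thickness`.
#' @return an object of class `depth_slab`.
#' @export
depth_slab <- function(layer, z_from, z_to) {
  stopifnot(layer >= 1, z_from >= 0, z_to > z_from)
  structure(list(layer = as.integer(layer), z_from = as.numeric(z_from),
                 z_to = as.numeric(z_to)),
            class = "depth_slab")
}

slab_absolute <- function(model, slab) {
  th <- vapply(model$layers, `[[`, 0, "thickness")
  if (slab$layer > length(th))
    stop("slab layer index exceeds the number of layers")
  if (slab$z_to > th[slab$layer])
    stop("slab extends below its layer")
  ztop <- c(0, cumsum(th))[slab$layer]
  c(ztop + slab$z_from, ztop + slab$z_to)
}

#' Read or write a head-model configuration
#'
#' The configuration is a nested key/value (YAML) file with a `layers`
#' list and optional `inclusion` block; see [make_phantom_scene()] for the
#' fields produced.
#'
#' @param path file path.
#' @return `read_head_config()` returns a [head_model()];
#'   `write_head_config()` returns `path` invisibly.
#' @export
read_head_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(l)
    head_layer(if (identical(l$thickness, "Inf") || is.null(l$thickness))
                 Inf else l$thickness,
               l$mus_prime, l$mua, l$refractive_index %||% 1.4,
               name = l$name))
  inc <- NULL
  if (!is.null(cfg$inclusion))
    inc <- inclusion_cylinder(cfg$inclusion$diameter,
                              unlist(cfg$inclusion$center),
                              cfg$inclusion$axis %||% "z",
                              if (identical(cfg$inclusion$length, "Inf") ||
                                  is.null(cfg$inclusion$length)) Inf
                              else cfg$inclusion$length,
                              cfg$inclusion$delta_mua %||% 0)
  head_model(layers, inc)
}

#' @rdname read_head_config
#' @param model a [head_model()].
#' @export
write_head_config <- function(model, path) {
  stopifnot(inherits(model, "head_model"))
  cfg <- list(layers = lapply(model$layers, function(l)
    list(name = l$name %||% "", thickness = if (is.finite(l$thickness))
      l$thickness else "Inf",
      mus_prime = l$mus_prime, mua = l$mua,
      refractive_index = l$refractive_index)))
  if (!is.null(model$inclusion)) {
    inc <- model$inclusion
    cfg$inclusion <- list(diameter = inc$diameter,
                          center = as.list(inc$center), axis = inc$axis,
                          length = if (is.finite(inc$length)) inc$length
                                   else "Inf",
                          delta_mua = inc$delta_mua)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
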