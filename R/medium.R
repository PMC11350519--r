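#' A single layer of a layered medium
#'
#' @param props an [optical_properties()] object.
#' @param thickness layer thickness in mm; `Inf` marks the semi-infinite
#'   bottom layer (only the last layer of a medium may, and must, be
#'   semi-infinite).
#' @return An object of class `layer`.
#' @export
layer <- function(props, thickness = Inf) {
  stopifnot(inherits(props, "optical_properties"),
            is.numeric(thickness), length(thickness) == 1L)
  if (!(thickness > 0)) stop("thickness must be > 0 (use Inf for the semi-infinite base)")
  structure(list(props = props, thickness = thickness), class = "layer")
}

#' A planar layered semi-infinite medium
#'
#' An ordered stack of parallel planar layers, top to bottom. The last layer
#' must be semi-infinite; all internal interfaces are index-matched (both
#' layers of the phantoms share the agar/Intralipid matrix), while the top
#' surface sees the ambient index.
#'
#' @param layers a list of [layer()] objects, top first.
#' @param ambient_n refractive index of the medium above the sample
#'   (default 1.0, air).
#' @return An object of class `layered_medium`.
#' @examples
#' top <- optical_properties(0.6, 2.9, 0.69)
#' bot <- optical_properties(0.03, 2.9, 0.69)
#' layered_medium(list(layer(top, 2), layer(bot)))
#' @export
layered_medium <- function(layers, ambient_n = 1.0) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (!all(vapply(layers, inherits, logical(1), "layer"))) {
    stop("layers must all be `layer` objects")
  }
  thick <- vapply(layers, function(l) l$thickness, numeric(1))
  nl <- length(thick)
  if (!is.infinite(thick[nl])) stop("the last layer must be semi-infinite (thickness = Inf)")
  if (nl > 1 && any(is.infinite(thick[-nl]))) {
    stop("only the last layer may be semi-infinite")
  }
  stopifnot(is.numeric(ambient_n), ambient_n >= 1 || ambient_n > 0)
  structure(list(layers = layers, ambient_n = ambient_n),
            class = "layered_medium")
}

#' Convenience constructors for monolayer and bilayer media
#'
#' @param props,top,bottom [optical_properties()] objects.
#' @param thickness top-layer thickness in mm (bilayer only).
#' @param ambient_n ambient refractive index (default air).
#' @return A [layered_medium()].
#' @export
monolayer_medium <- function(props, ambient_n = 1.0) {
  layered_medium(list(layer(props)), ambient_n = ambient_n)
}

#' @rdname monolayer_medium
#' @export
bilayer_medium <- function(top, bottom, thickness = 2, ambient_n = 1.0) {
  layered_medium(list(layer(top, thickness), layer(bottom)),
                 ambient_n = ambient_n)
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> %d layer(s), ambient n = %g\n",
              length(x$layers), x$ambient_n))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] mu_a = %g, mu_s = %g, g = %g, n = %g, thickness = %s mm\n",
                i, l$props$mu_a, l$props$mu_s, l$props$g, l$props$n,
                if (is.infinite(l$thickness)) "Inf" else format(l$thickness)))
  }
  invisible(x)
}

#' Radial detection grid for diffuse-reflectance scoring
#'
#' Half-open annular bins [rho_i, rho_i + d_rho), reported at bin centers.
#' The default (2 to 12 mm every 0.2 mm) matches the radial scan of a
#' fiber-based diffuse-reflectance bench.
#'
#' @param rho_min inner edge of the first annulus (mm), >= 0.
#' @param rho_max outer edge of the last annulus (mm).
#' @param d_rho bin width (mm).
#' @return An object of class `detection_grid` with precomputed bin `centers`,
#'   `edges` and annulus `areas` (mm^2).
#' @export
detection_grid <- function(rho_min = 2, rho_max = 12, d_rho = 0.2) {
  stopifnot(rho_min >= 0, rho_max > rho_min, d_rho > 0)
  nbins <- round((rho_max - rho_min) / d_rho)
  if (abs(nbins * d_rho - (rho_max - rho_min)) > 1e-9) {
    stop("(rho_max - rho_min) must be an integer multiple of d_rho")
  }
  edges <- rho_min + d_rho * (0:nbins)
  structure(
    list(rho_min = rho_min, rho_max = rho_max, d_rho = d_rho, nbins = nbins,
         centers = edges[-length(edges)] + d_rho / 2,
         edges = edges,
         areas = pi * diff(edges^2)),
    class = "detection_grid")
}

#' Monte Carlo run configuration
#'
#' @param n_photons number of launched photons. The package default is 1e7,
#'   at which the analysis endpoints (fitted slopes over 2-10 mm, crossover
#'   points) are stable; larger counts reduce far-bin noise further.
#' @param seed integer-valued seed for the transport RNG; identical
#'   configurations (including seed) reproduce bit-identical profiles.
#' @param weight_threshold photon weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival survival probability of the roulette
#'   (default 0.1); survivors have their weight divided by this value, so the
#'   termination is unbiased.
#' @param max_interactions hard safety cap on interactions per photon.
#' @param beam_radius radius (mm) of a flat-top illumination beam; 0
#'   (default) launches an ideal pencil beam at the origin. Useful for
#'   sensitivity studies with a finite source fiber.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 1e7, seed = 1,
                       weight_threshold = 1e-4, roulette_survival = 0.1,
                       max_interactions = 1e6, beam_radius = 0) {
  stopifnot(n_photons >= 1,
            weight_threshold > 0, weight_threshold < 1,
            roulette_survival > 0, roulette_survival < 1,
            max_interactions >= 1, beam_radius >= 0)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(n_photons = n_photons, seed = seed,
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 max_interactions = max_interactions,
                 beam_radius = beam_radius),
            class = "sim_config")
}
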