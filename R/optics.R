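#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of one homogeneous medium. All derived
#' transport coefficients used elsewhere in the package (reduced scattering,
#' effective attenuation, transport mean free path) are computed from these
#' four numbers. Units are fixed: coefficients in mm^-1, distances in mm.
#'
#' @param mu_a absorption coefficient (mm^-1), non-negative.
#' @param mu_s scattering coefficient (mm^-1), strictly positive.
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   deflection angle), in (-1, 1). Tissue-mimicking Intralipid phantoms are
#'   strongly forward scattering (g around 0.7).
#' @param n refractive index of the medium, >= 1. Default 1.4, the usual
#'   value adopted for soft tissue and agar/Intralipid phantoms.
#' @param label optional character label carried through serialization.
#'
#' @return An object of class `optical_properties`: a list with fields
#'   `mu_a`, `mu_s`, `g`, `n`, `label` and the derived `mu_s_prime`
#'   (= mu_s * (1 - g), full precision).
#' @examples
#' op <- optical_properties(mu_a = 0.12, mu_s = 2.9, g = 0.69)
#' op$mu_s_prime
#' effective_attenuation(op$mu_a, op$mu_s_prime)
#' @export
optical_properties <- function(mu_a, mu_s, g, n = 1.4, label = NULL) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s <= 0) stop("mu_s must be > 0")
  if (g <= -1 || g >= 1) stop("g must lie strictly inside (-1, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
         mu_s_prime = mu_s * (1 - g),
         label = if (is.null(label)) NULL else as.character(label)),
    class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties%s> mu_a = %g, mu_s = %g, g = %g, n = %g (mu_s' = %g mm^-1)\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    x$mu_a, x$mu_s, x$g, x$n, x$mu_s_prime))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' Computes mu_s' = mu_s * (1 - g), the similarity-scaled scattering
#' coefficient governing diffuse light transport. Returned at full floating
#' precision; use [truncate_decimals()] when mirroring two-decimal design
#' values.
#'
#' @param props an [optical_properties()] object.
#' @return reduced scattering coefficient (mm^-1).
#' @examples
#' reduced_scattering(optical_properties(0, 2.9, 0.69))  # 0.899
#' @export
reduced_scattering <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  props$mu_s * (1 - props$g)
}

#' Effective attenuation coefficient of the diffusion approximation
#'
#' mu_eff = sqrt(3 * mu_a * (mu_s' + mu_a)). In the multiple-scattering
#' regime the spatially resolved diffuse reflectance decays asymptotically as
#' exp(-mu_eff * rho), so mu_eff sets the slope of ln(R * rho^m) profiles.
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0.
#' @param mu_s_prime reduced scattering coefficient (mm^-1), > 0.
#' @return effective attenuation coefficient (mm^-1); 0 iff `mu_a == 0`.
#' @examples
#' effective_attenuation(0.12, 0.89)
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s_prime))
  if (any(mu_a < 0)) stop("mu_a must be >= 0")
  if (any(mu_s_prime <= 0)) stop("mu_s_prime must be > 0")
  sqrt(3 * mu_a * (mu_s_prime + mu_a))
}

#' Far-field noise-limit distance (k transport mean free paths)
#'
#' The practical detection limit of a diffuse-reflectance profile sits around
#' five transport mean free paths, with MFP' = 1 / mu_eff. This helper
#' returns k * MFP' = k / mu_eff for the medium that dominates the far-field
#' slope (the bottom layer, for a bilayer sample).
#'
#' @param mu_a absorption coefficient (mm^-1), strictly positive (a
#'   non-absorbing medium has no finite attenuation length).
#' @param mu_s_prime reduced scattering coefficient (mm^-1), > 0.
#' @param k multiplier, default 5 (the conventional noise limit).
#' @return distance (mm).
#' @examples
#' noise_limit_distance(0.12, 0.89)  # about 8.29 mm
#' @export
noise_limit_distance <- function(mu_a, mu_s_prime, k = 5) {
  stopifnot(is.numeric(k), all(k > 0))
  if (any(mu_a <= 0)) {
    stop("mu_a must be > 0: a non-absorbing medium has no finite noise-limit distance")
  }
  k / effective_attenuation(mu_a, mu_s_prime)
}

#' Truncate (not round) to a fixed number of decimals
#'
#' Reporting helper used when mirroring two-decimal design values, which are
#' truncated rather than rounded (2.9 * 0.31 = 0.899 is reported as 0.89).
#'
#' @param x numeric vector.
#' @param digits decimals kept, default 2.
#' @return truncated values.
#' @examples
#' truncate_decimals(0.899)  # 0.89
#' @export
truncate_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Serialize optical properties to / from JSON config entries
#'
#' @param props an [optical_properties()] object.
#' @param json a JSON string or file path with fields
#'   `mu_a`, `mu_s`, `g`, `n` and optional `label`.
#' @return `optical_properties_to_json()` returns a JSON string;
#'   `optical_properties_from_json()` returns an [optical_properties()] object.
#' @examples
#' js <- optical_properties_to_json(optical_properties(0.09, 2.9, 0.69))
#' optical_properties_from_json(js)
#' @export
optical_properties_to_json <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  jsonlite::toJSON(
    list(mu_a = props$mu_a, mu_s = props$mu_s, g = props$g, n = props$n,
         label = props$label),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname optical_properties_to_json
#' @export
optical_properties_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  optical_properties(mu_a = x$mu_a, mu_s = x$mu_s, g = x$g,
                     n = if (is.null(x$n)) 1.4 else x$n, label = x$label)
}
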