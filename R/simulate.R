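#' Simulate a spatially resolved diffuse-reflectance profile
#'
#' Runs weighted-photon Monte Carlo transport through a layered semi-infinite
#' medium and scores the photons re-emitted through the top surface into
#' radial annular bins. The transport follows the standard tissue-optics
#' scheme: a pencil beam enters perpendicular to the surface at the origin;
#' the specular fraction is removed at entry; step lengths are sampled from
#' the current layer's total interaction coefficient, with partial steps
#' rescaled across index-matched internal interfaces; each interaction
#' deposits the fraction mu_a/mu_t of the photon weight and redirects the
#' photon by Henyey-Greenstein sampling; the top surface applies unpolarized
#' Fresnel reflection (including total internal reflection); low-weight
#' photons are terminated unbiasedly by Russian roulette.
#'
#' @param medium a [layered_medium()].
#' @param grid a [detection_grid()].
#' @param config a [sim_config()].
#' @param matched_boundary if `TRUE`, the surface is index-matched (no
#'   specular loss, no Fresnel reflection) — the configuration under which
#'   the medium matches the boundary-free diffusion approximation most
#'   closely. Default `FALSE` (air above an n = 1.4 sample).
#'
#' @return An object of class `dr_profile`: a list with numeric vectors
#'   `rho` (bin centers, mm), `R` (diffuse reflectance per unit area per
#'   launched photon, mm^-2), `R_se` (per-bin standard error), `hits`
#'   (photons scored per bin), scalar `n_photons`, an `audit` list with the
#'   energy bookkeeping (specular, absorbed, roulette_lost, cap_lost,
#'   outside-grid and scored exit weight; their sum equals the launched
#'   weight), and `meta` describing medium, grid and config.
#' @examples
#' \donttest{
#' med <- monolayer_medium(optical_properties(0.09, 2.9, 0.69))
#' prof <- simulate_dr(med, detection_grid(), sim_config(n_photons = 1e5, seed = 7))
#' head(as.data.frame(prof))
#' }
#' @export
simulate_dr <- function(medium, grid, config, matched_boundary = FALSE) {
  stopifnot(inherits(medium, "layered_medium"),
            inherits(grid, "detection_grid"),
            inherits(config, "sim_config"))
  props <- lapply(medium$layers, `[[`, "props")
  res <- .mc_transport(
    mu_a = vapply(props, `[[`, numeric(1), "mu_a"),
    mu_s = vapply(props, `[[`, numeric(1), "mu_s"),
    g = vapply(props, `[[`, numeric(1), "g"),
    n_layer = vapply(props, `[[`, numeric(1), "n"),
    thickness = vapply(medium$layers, `[[`, numeric(1), "thickness"),
    ambient_n = medium$ambient_n,
    rho_min = grid$rho_min, rho_max = grid$rho_max, d_rho = grid$d_rho,
    n_photons = config$n_photons, seed = config$seed,
    weight_threshold = config$weight_threshold,
    roulette_survival = config$roulette_survival,
    max_interactions = config$max_interactions,
    matched_boundary = matched_boundary,
    beam_radius = if (is.null(config$beam_radius)) 0 else config$beam_radius)

  N <- config$n_photons
  denom <- grid$areas * N
  R <- res$sum_w / denom
  # per-bin variance of the scored sum: sum w^2 - (sum w)^2 / N
  var_sum <- pmax(res$sum_w2 - res$sum_w^2 / N, 0)
  R_se <- sqrt(var_sum) / denom

  structure(
    list(rho = grid$centers, R = R, R_se = R_se, hits = res$hits,
         n_photons = N,
         audit = list(specular = res$specular, absorbed = res$absorbed,
                      roulette_lost = res$roulette_lost,
                      cap_lost = res$cap_lost, outside = res$outside,
                      scored = res$escaped - res$outside,
                      escaped = res$escaped,
                      interactions = res$interactions),
         meta = list(medium = medium, grid = grid, config = config,
                     matched_boundary = matched_boundary)),
    class = "dr_profile")
}

#' @export
print.dr_profile <- function(x, ...) {
  cat(sprintf(
    "<dr_profile> %d bins over [%g, %g) mm, %s photons, %.1f%% of launched weight scored\n",
    length(x$rho), x$meta$grid$rho_min, x$meta$grid$rho_max,
    format(x$n_photons, big.mark = ","),
    100 * x$audit$scored / x$n_photons))
  invisible(x)
}

#' @export
as.data.frame.dr_profile <- function(x, ...) {
  data.frame(rho_mm = x$rho, R_per_mm2 = x$R, R_se = x$R_se, hits = x$hits)
}

#' Energy audit of a simulated profile
#'
#' Sums the scored, absorbed and terminated photon weight and compares with
#' the launched weight; the relative closure error is zero up to floating
#' accumulation (used as a correctness check on the transport kernel).
#'
#' @param profile a [simulate_dr()] result.
#' @return list with `total` (recovered weight), `launched`, and
#'   `relative_error`.
#' @export
energy_audit <- function(profile) {
  stopifnot(inherits(profile, "dr_profile"))
  a <- profile$audit
  total <- a$specular + a$escaped + a$absorbed + a$roulette_lost + a$cap_lost
  list(total = total, launched = profile$n_photons,
       relative_error = abs(total - profile$n_photons) / profile$n_photons)
}

#' Pool diffuse-reflectance profiles simulated with distinct seeds
#'
#' Long runs can be sharded across seeds and pooled: the pooled reflectance
#' is the launched-photon-weighted mean and the standard errors combine in
#' quadrature, so pooling N equal shards shrinks R_se by about 1/sqrt(N).
#'
#' @param profiles list of [simulate_dr()] results on identical grids.
#' @return a pooled `dr_profile`.
#' @export
combine_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "dr_profile")))
  p1 <- profiles[[1]]
  if (length(profiles) == 1L) return(p1)
  for (p in profiles[-1]) {
    if (length(p$rho) != length(p1$rho) || any(abs(p$rho - p1$rho) > 1e-12)) {
      stop("profiles must share an identical detection grid")
    }
  }
  seeds <- vapply(profiles, function(p) p$meta$config$seed, numeric(1))
  if (anyDuplicated(seeds)) stop("shards must use distinct seeds")
  N <- vapply(profiles, `[[`, numeric(1), "n_photons")
  Ntot <- sum(N)
  R <- Reduce(`+`, Map(function(p, n) p$R * n, profiles, N)) / Ntot
  R_se <- sqrt(Reduce(`+`, Map(function(p, n) (p$R_se * n)^2, profiles, N))) / Ntot
  hits <- Reduce(`+`, lapply(profiles, `[[`, "hits"))
  audit <- as.list(Reduce(`+`, lapply(profiles, function(p) unlist(p$audit))))
  out <- p1
  out$R <- R
  out$R_se <- R_se
  out$hits <- hits
  out$n_photons <- Ntot
  out$audit <- audit
  out$meta$config$n_photons <- Ntot
  out$meta$config$seed <- seeds
  out
}
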