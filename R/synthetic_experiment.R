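#' Build the monolayer/bilayer phantom grid
#'
#' Deterministic manifest of the simulated study: one monolayer per
#' absorption value (low and high sets together) and one bilayer per
#' (high top, low bottom) combination, all sharing the scattering
#' properties, top-layer thickness and detection grid. The defaults are the
#' study conditions: low set {0.03, 0.09, 0.12} mm^-1, high set
#' {0.24, 0.41, 0.6} mm^-1, mu_s = 2.9 mm^-1, g = 0.69 (mu_s' = 0.89),
#' T = 2 mm, detection 2-12 mm every 0.2 mm — nine bilayers in all.
#'
#' @param mu_a_low bottom-layer (low) absorption values (mm^-1).
#' @param mu_a_high top-layer (high) absorption values (mm^-1); must exceed
#'   every low value and not overlap the low set.
#' @param mu_s,g scattering coefficient and anisotropy shared by all layers.
#' @param T top-layer thickness (mm).
#' @param grid a [detection_grid()].
#' @param n,ambient_n refractive indices of the phantom material and the
#'   ambient medium.
#' @return An object of class `phantom_grid`: list with data frames
#'   `monolayers` (label, mu_a) and `bilayers` (label, mu_a_top,
#'   mu_a_bottom, mono_label), plus `shared` parameters. Labels are unique
#'   and sorted by absorption.
#' @export
build_grid <- function(mu_a_low = c(0.03, 0.09, 0.12),
                       mu_a_high = c(0.24, 0.41, 0.6),
                       mu_s = 2.9, g = 0.69, T = 2,
                       grid = detection_grid(),
                       n = 1.4, ambient_n = 1.0) {
  stopifnot(length(mu_a_low) >= 1, length(mu_a_high) >= 1,
            all(mu_a_low > 0), all(mu_a_high > 0),
            inherits(grid, "detection_grid"), T > 0)
  if (length(intersect(mu_a_low, mu_a_high)) > 0) {
    stop("low and high absorption sets must be disjoint")
  }
  if (min(mu_a_high) <= max(mu_a_low)) {
    stop("every high absorption value must exceed every low value")
  }
  mu_a_low <- sort(mu_a_low)
  mu_a_high <- sort(mu_a_high)
  lab <- function(x) sprintf("%.2f", x)
  mono <- data.frame(
    label = paste0("mono_", lab(c(mu_a_low, mu_a_high))),
    mu_a = c(mu_a_low, mu_a_high),
    stringsAsFactors = FALSE)
  bi <- expand.grid(mu_a_bottom = mu_a_low, mu_a_top = mu_a_high,
                    KEEP.OUT.ATTRS = FALSE)
  bi <- bi[order(bi$mu_a_top, bi$mu_a_bottom), , drop = FALSE]
  bi <- data.frame(
    label = paste0("bi_", lab(bi$mu_a_top), "_", lab(bi$mu_a_bottom)),
    mu_a_top = bi$mu_a_top, mu_a_bottom = bi$mu_a_bottom,
    mono_label = paste0("mono_", lab(bi$mu_a_top)),
    stringsAsFactors = FALSE)
  rownames(bi) <- NULL
  structure(
    list(monolayers = mono, bilayers = bi,
         shared = list(mu_s = mu_s, g = g, T = T, grid = grid,
                       n = n, ambient_n = ambient_n)),
    class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("<phantom_grid> %d monolayers + %d bilayers (mu_s = %g, g = %g, T = %g mm)\n",
              nrow(x$monolayers), nrow(x$bilayers),
              x$shared$mu_s, x$shared$g, x$shared$T))
  invisible(x)
}

#' Agar correction of a reduced scattering coefficient
#'
#' Solid agar phantoms scatter less than the equivalent liquid Intralipid
#' dilution: the design reduced-scattering value must be multiplied by 0.7
#' when the suspension is gelled. Recipe-design helper only — the phantom
#' grid takes final (already corrected) coefficients directly.
#'
#' @param musp_raw reduced scattering coefficient of the liquid dilution
#'   (mm^-1), > 0.
#' @return corrected coefficient, 0.7 * musp_raw.
#' @export
agar_corrected_musp <- function(musp_raw) {
  if (any(musp_raw <= 0)) stop("musp_raw must be > 0")
  0.7 * musp_raw
}

#' Detector-noise model for emulated measurements
#'
#' Real radial scans differ from clean Monte Carlo output in two ways: a
#' multiplicative per-bin fluctuation (source/detector gain, coupling) and
#' an additive floor (dark counts, stray light) that dominates once the
#' signal has decayed far enough — producing the far-distance noise region
#' in which the profile departs from its trend line.
#'
#' @param multiplicative_cv relative standard deviation per bin, >= 0.
#'   Default 0.03.
#' @param additive_floor floor level in reflectance units (mm^-2), >= 0.
#'   See [default_noise_floor()] for the study default.
#' @param seed RNG seed for reproducible noise draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.03, additive_floor = 0,
                        seed = 1) {
  stopifnot(multiplicative_cv >= 0, additive_floor >= 0)
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_floor = additive_floor, seed = seed),
            class = "noise_model")
}

#' Study default for the additive noise floor
#'
#' Sets the floor to the clean model reflectance, extrapolated from a
#' monolayer profile of the weakest-absorbing bottom-layer medium, at that
#' medium's own five-MFP' distance. Because all profiles share a similar
#' amplitude, each medium's signal then crosses the floor near its own
#' 5 / mu_eff distance, so the onset of the emulated noise region lands
#' where the noise-limit rule predicts.
#'
#' @param profile a clean monolayer `dr_profile` of the weakest-absorbing
#'   bottom medium.
#' @param mu_a,mu_s_prime optical coefficients of that medium (mm^-1).
#' @param m exponent used for the extrapolation fit (default 1).
#' @param fit_range radial range (mm) of the fit, default c(2, 8).
#' @return floor level (mm^-2).
#' @export
default_noise_floor <- function(profile, mu_a, mu_s_prime, m = 1,
                                fit_range = c(2, 8)) {
  stopifnot(inherits(profile, "dr_profile"))
  logp <- to_log_profile(profile, m = m)
  fit <- fit_global_slope(logp, fit_range)
  rho_n <- noise_limit_distance(mu_a, mu_s_prime, k = 5)
  exp(fit$intercept + fit$slope * rho_n) / rho_n^m
}

#' Emulate a noisy measured profile
#'
#' Applies the [noise_model()] to a clean profile:
#' R' = R * (1 + eps) + floor * |eta|, with eps zero-mean Gaussian of
#' standard deviation `multiplicative_cv` and eta standard normal; results
#' below the floor's scale are clipped at the floor (at zero when the floor
#' is zero), as a rectifying detector would. Reproducible for a fixed
#' model seed; R's global RNG state is left untouched.
#'
#' @param profile a `dr_profile`.
#' @param noise a [noise_model()].
#' @return a `dr_profile` with perturbed `R` and inflated `R_se`.
#' @export
emulate_measurement <- function(profile, noise) {
  stopifnot(inherits(profile, "dr_profile"), inherits(noise, "noise_model"))
  if (noise$multiplicative_cv == 0 && noise$additive_floor == 0) {
    return(profile)
  }
  nb <- length(profile$R)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)
  eps <- stats::rnorm(nb, 0, noise$multiplicative_cv)
  eta <- abs(stats::rnorm(nb))
  R <- profile$R * (1 + eps) + noise$additive_floor * eta
  R <- pmax(R, noise$additive_floor)
  out <- profile
  out$R <- R
  # first-order error model: MC error, multiplicative jitter, floor spread
  out$R_se <- sqrt(profile$R_se^2 +
                   (noise$multiplicative_cv * profile$R)^2 +
                   (noise$additive_floor^2 * (1 - 2 / pi)))
  out$meta$noise <- noise
  out
}

#' Run the full simulated crossover-point study
#'
#' Simulates the phantom grid, extracts one crossover point per bilayer
#' (against the monolayer matching its top layer) and fits the linear
#' relation of Cp versus sqrt(mu_a2 / mu_a1). Optionally repeats the
#' extraction on noise-emulated profiles.
#'
#' Per-configuration seeds fan out from `master_seed` as
#' `master_seed * 10007 + index` (index = position in the manifest; noise
#' seeds add 500), so any sub-study can be reproduced in isolation.
#'
#' @param grid a [build_grid()] manifest.
#' @param sim a [sim_config()]; its `seed` is ignored in favor of the
#'   derived per-configuration seeds.
#' @param cp a [cp_config()].
#' @param m log-profile exponent, default 1.
#' @param noise optional [noise_model()]; `TRUE` selects the default model
#'   (cv 0.03, floor from [default_noise_floor()] on the weakest bottom
#'   medium — requires `monolayers = "all"`).
#' @param monolayers `"all"` (default: simulate every monolayer, as in the
#'   full study) or `"top"` (only the monolayers needed as bilayer
#'   references).
#' @param master_seed master seed of the study.
#' @return An object of class `cp_study`: list with `profiles` (named list
#'   of `dr_profile`s), `cp_results` (named list, one per bilayer),
#'   `relation` (a [fit_cp_relation()] result), `points` (the fitted data
#'   frame), optional `noisy` (cp_results + relation on emulated profiles),
#'   and `manifest` (data frame of configurations and seeds).
#' @export
run_study <- function(grid, sim = sim_config(), cp = cp_config(), m = 1,
                      noise = NULL, monolayers = c("all", "top"),
                      master_seed = 1) {
  stopifnot(inherits(grid, "phantom_grid"), inherits(sim, "sim_config"),
            inherits(cp, "cp_config"))
  monolayers <- match.arg(monolayers)
  sh <- grid$shared
  mono_tab <- grid$monolayers
  if (monolayers == "top") {
    mono_tab <- mono_tab[mono_tab$label %in% grid$bilayers$mono_label, ,
                         drop = FALSE]
  }
  if (!all(grid$bilayers$mono_label %in% mono_tab$label)) {
    stop("every bilayer needs its top-layer monolayer partner in the grid")
  }

  manifest <- data.frame(
    label = c(mono_tab$label, grid$bilayers$label),
    kind = c(rep("monolayer", nrow(mono_tab)),
             rep("bilayer", nrow(grid$bilayers))),
    stringsAsFactors = FALSE)
  manifest$index <- seq_len(nrow(manifest))
  manifest$seed <- master_seed * 10007 + manifest$index

  op <- function(mu_a) optical_properties(mu_a, sh$mu_s, sh$g, n = sh$n)
  profiles <- vector("list", nrow(manifest))
  names(profiles) <- manifest$label
  for (i in seq_len(nrow(mono_tab))) {
    medium <- monolayer_medium(op(mono_tab$mu_a[i]), ambient_n = sh$ambient_n)
    cfg <- sim; cfg$seed <- manifest$seed[manifest$label == mono_tab$label[i]]
    profiles[[mono_tab$label[i]]] <- simulate_dr(medium, sh$grid, cfg)
  }
  for (i in seq_len(nrow(grid$bilayers))) {
    b <- grid$bilayers[i, ]
    medium <- bilayer_medium(op(b$mu_a_top), op(b$mu_a_bottom),
                             thickness = sh$T, ambient_n = sh$ambient_n)
    cfg <- sim; cfg$seed <- manifest$seed[manifest$label == b$label]
    profiles[[b$label]] <- simulate_dr(medium, sh$grid, cfg)
  }

  extract_all <- function(profs) {
    logs <- lapply(profs, to_log_profile, m = m)
    res <- vector("list", nrow(grid$bilayers))
    names(res) <- grid$bilayers$label
    for (i in seq_len(nrow(grid$bilayers))) {
      b <- grid$bilayers[i, ]
      res[[b$label]] <- extract_cp(logs[[b$label]], logs[[b$mono_label]], cp)
    }
    res
  }
  points_from <- function(cps) {
    data.frame(
      x = sqrt_ratio(grid$bilayers$mu_a_bottom, grid$bilayers$mu_a_top),
      cp = vapply(cps, `[[`, numeric(1), "cp"),
      label = grid$bilayers$label,
      stringsAsFactors = FALSE)
  }

  cp_results <- extract_all(profiles)
  points <- points_from(cp_results)
  relation <- if (sum(is.finite(points$cp)) >= 3) fit_cp_relation(points) else NULL

  noisy <- NULL
  if (!is.null(noise) && !identical(noise, FALSE)) {
    if (isTRUE(noise)) {
      weakest <- grid$monolayers$label[which.min(grid$monolayers$mu_a)]
      if (!weakest %in% names(profiles)) {
        stop("default noise floor needs monolayers = \"all\" (weakest bottom medium)")
      }
      floor_val <- default_noise_floor(
        profiles[[weakest]], min(grid$monolayers$mu_a),
        sh$mu_s * (1 - sh$g), m = m)
      noise <- noise_model(additive_floor = floor_val, seed = master_seed)
    }
    stopifnot(inherits(noise, "noise_model"))
    noisy_profiles <- profiles
    for (i in seq_along(profiles)) {
      nm <- noise
      nm$seed <- master_seed * 10007 + 500 + manifest$index[i]
      noisy_profiles[[i]] <- emulate_measurement(profiles[[i]], nm)
    }
    noisy_cp <- extract_all(noisy_profiles)
    noisy <- list(profiles = noisy_profiles, cp_results = noisy_cp,
                  points = points_from(noisy_cp),
                  relation = tryCatch(fit_cp_relation(points_from(noisy_cp)),
                                      error = function(e) NULL),
                  noise = noise)
  }

  structure(
    list(profiles = profiles, cp_results = cp_results, points = points,
         relation = relation, noisy = noisy, manifest = manifest,
         settings = list(grid = grid, sim = sim, cp = cp, m = m,
                         master_seed = master_seed)),
    class = "cp_study")
}

#' @export
print.cp_study <- function(x, ...) {
  cat(sprintf("<cp_study> %d profiles, %d crossover points\n",
              length(x$profiles), length(x$cp_results)))
  if (!is.null(x$relation)) print(x$relation)
  invisible(x)
}
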