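# Shared fixtures; built in code, cached per session so expensive Monte Carlo
# runs are shared between test blocks.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

phantom_props <- function(mu_a) optical_properties(mu_a, 2.9, 0.69)

# dr_profile built from the closed-form reflectance model (noiseless fixture)
model_profile <- function(grid = detection_grid(), C1 = 1, m = 1, mu_eff = 0.5,
                          R_se = 0) {
  R <- model_reflectance(grid$centers, C1, m, mu_eff)
  structure(list(rho = grid$centers, R = R,
                 R_se = rep(R_se, length(R)) * R,
                 hits = rep(NA_real_, length(R)),
                 n_photons = NA_real_, audit = NULL,
                 meta = list(grid = grid)),
            class = "dr_profile")
}

# piecewise-linear log profile: slope s1 up to rho0, s2 beyond (continuous)
two_segment_logp <- function(s1, s2, rho0, grid = detection_grid(),
                             y0 = 0, m = 1) {
  rho <- grid$centers
  y <- ifelse(rho <= rho0,
              y0 + s1 * (rho - rho[1]),
              y0 + s1 * (rho0 - rho[1]) + s2 * (rho - rho0))
  log_profile(rho, y, m = m)
}

mono_sim <- function(mu_a, n_photons, seed) {
  cached(sprintf("mono_%g_%g_%g", mu_a, n_photons, seed), {
    simulate_dr(monolayer_medium(phantom_props(mu_a)), detection_grid(),
                sim_config(n_photons = n_photons, seed = seed))
  })
}

bilayer_sim <- function(mu_a_top, mu_a_bottom, n_photons, seed, T = 2) {
  cached(sprintf("bi_%g_%g_%g_%g_%g", mu_a_top, mu_a_bottom, n_photons, seed, T), {
    simulate_dr(bilayer_medium(phantom_props(mu_a_top),
                               phantom_props(mu_a_bottom), thickness = T),
                detection_grid(), sim_config(n_photons = n_photons, seed = seed))
  })
}
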