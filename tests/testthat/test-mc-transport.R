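test_that("identical configurations reproduce bit-identical profiles", {
  med <- monolayer_medium(phantom_props(0.12))
  g <- detection_grid()
  p1 <- simulate_dr(med, g, sim_config(1e4, seed = 5))
  p2 <- simulate_dr(med, g, sim_config(1e4, seed = 5))
  expect_identical(p1$R, p2$R)
  expect_identical(p1$R_se, p2$R_se)
  p3 <- simulate_dr(med, g, sim_config(1e4, seed = 6))
  expect_false(identical(p1$R, p3$R))
})

test_that("energy bookkeeping closes to high relative accuracy", {
  for (med in list(monolayer_medium(phantom_props(0.09)),
                   bilayer_medium(phantom_props(0.41), phantom_props(0.03)))) {
    p <- simulate_dr(med, detection_grid(), sim_config(1e5, seed = 9))
    expect_lt(energy_audit(p)$relative_error, 1e-6)
  }
})

test_that("a bilayer of identical layers equals the monolayer bit for bit", {
  # the internal interface of an index-matched, equal-mu_t stack must be
  # transparent to the transport: same seed, same paths, same scores
  g <- detection_grid()
  pm <- simulate_dr(monolayer_medium(phantom_props(0.09)), g, sim_config(1e5, seed = 13))
  pb <- simulate_dr(bilayer_medium(phantom_props(0.09), phantom_props(0.09)), g,
                    sim_config(1e5, seed = 13))
  expect_identical(pm$R, pb$R)
})

test_that("halving the bin width and re-aggregating reproduces the coarse profile", {
  med <- monolayer_medium(phantom_props(0.12))
  cfg <- sim_config(1e5, seed = 17)
  coarse <- simulate_dr(med, detection_grid(2, 12, 0.2), cfg)
  fine <- simulate_dr(med, detection_grid(2, 12, 0.1), cfg)
  # area-weighted pairwise aggregation of fine annuli
  fine_area <- fine$meta$grid$areas
  agg_R <- (fine$R * fine_area)[c(TRUE, FALSE)] + (fine$R * fine_area)[c(FALSE, TRUE)]
  expect_equal(agg_R / coarse$meta$grid$areas, coarse$R, tolerance = 1e-12)
  expect_equal(fine$hits[c(TRUE, FALSE)] + fine$hits[c(FALSE, TRUE)], coarse$hits)
})

test_that("pooling shards sums photons and shrinks standard errors as 1/sqrt(N)", {
  med <- monolayer_medium(phantom_props(0.09))
  g <- detection_grid()
  shards <- lapply(1:4, function(s) simulate_dr(med, g, sim_config(2e5, seed = 100 + s)))
  pooled <- combine_profiles(shards)
  expect_identical(combine_profiles(shards[1]), shards[[1]])
  expect_equal(pooled$n_photons, 8e5)
  ok <- shards[[1]]$hits >= 100
  ratio <- pooled$R_se[ok] / shards[[1]]$R_se[ok]
  expect_lt(abs(median(ratio) - 0.5), 0.1)
  expect_error(combine_profiles(list(shards[[1]], shards[[1]])), "distinct seeds")
  fine <- simulate_dr(med, detection_grid(2, 12, 0.1), sim_config(2e5, seed = 105))
  expect_error(combine_profiles(list(shards[[1]], fine)), "grid")
})

test_that("fitted log-slopes steepen strictly with absorption", {
  slopes <- vapply(c(0.03, 0.09, 0.12, 0.24, 0.41, 0.6), function(mu_a) {
    p <- mono_sim(mu_a, 1e6, seed = 41)
    fit_global_slope(to_log_profile(p, m = 1), c(2, 8))$slope
  }, numeric(1))
  expect_true(all(diff(-slopes) > 0))
})

test_that("beyond the crossover a bilayer's local slope approaches the bottom layer's", {
  pb <- bilayer_sim(0.41, 0.03, 1e6, seed = 43)
  p_top <- mono_sim(0.41, 1e6, seed = 41)
  p_bot <- mono_sim(0.03, 1e6, seed = 41)
  ls_b <- local_slopes(to_log_profile(pb), window = 2)
  ls_bot <- local_slopes(to_log_profile(p_bot), window = 2)
  ls_top <- local_slopes(to_log_profile(p_top), window = 2)
  far <- ls_b$rho >= 7 & ls_b$rho <= 9
  sb <- mean(ls_b$slope[far])
  sbot <- mean(ls_bot$slope[ls_bot$rho >= 7 & ls_bot$rho <= 9])
  stop_top <- mean(ls_top$slope[ls_top$rho >= 7 & ls_top$rho <= 9])
  # far-field slope sits near the bottom-layer slope, far from the top-layer one
  expect_lt(abs(sb - sbot), 0.2 * abs(sbot - stop_top))
})

test_that("unphysical media and grids are rejected before launch", {
  expect_error(layered_medium(list(layer(phantom_props(0.1), 2))), "semi-infinite")
  expect_error(layered_medium(list(layer(phantom_props(0.1), Inf),
                                   layer(phantom_props(0.2), Inf))), "last layer")
  expect_error(detection_grid(2, 2, 0.2))
  expect_error(detection_grid(2, 12, 0.3), "multiple")
})
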