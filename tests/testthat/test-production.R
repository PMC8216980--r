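test_that("secondary production matches its closed algebraic form", {
  expect_equal(secondary_production(1, 1), 1.12 * 10^(-0.73),
               tolerance = 1e-14)
  expect_equal(secondary_production(10, 0), 0)
  # the two algebraic forms of the regression agree on a log-spaced grid
  M <- 10^seq(-2, 3, length.out = 41)
  N <- 10^seq(-1, 3, length.out = 41)
  grid <- expand.grid(M = M, N = N)
  lhs <- secondary_production(grid$M, grid$N)
  rhs <- 1.12 * 10^(-0.73) * grid$M^0.77 * grid$N
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # doubling body mass scales production by 2^0.77
  expect_equal(secondary_production(2, 5) / secondary_production(1, 5),
               2^0.77, tolerance = 1e-12)
  # linear in abundance, increasing and concave in mass
  expect_equal(secondary_production(3, 14), 7 * secondary_production(3, 2),
               tolerance = 1e-12)
  sp <- secondary_production(M, 1)
  expect_true(all(diff(sp) > 0))
  # concavity (exponent 0.77 < 1) on an evenly spaced mass grid
  sp_lin <- secondary_production(seq(0.5, 100, by = 0.5), 1)
  expect_true(all(diff(diff(sp_lin)) < 0))
  expect_error(secondary_production(-1, 1), "M must be")
})

test_that("unit conversions use the fixed quotients", {
  expect_equal(dw_to_carbon(2.3), 1)
  expect_equal(dw_to_carbon(0), 0)
  expect_equal(dw_to_carbon(1), 1 / 2.3)
  expect_equal(gpp_o2_to_carbon(1000), 320)
  expect_equal(gpp_o2_to_carbon(0), 0)
  expect_equal(gpp_o2_to_carbon(3.125), 1)
  # round trip to machine precision
  x <- c(0.1, 1, 10, 1000)
  expect_equal(gpp_o2_to_carbon(x) / 0.32, x, tolerance = 1e-15)
  expect_error(conversion_constants(o2_to_c = 0), "must be > 0")
})

test_that("the light-response model reproduces the hand-computed layer", {
  prof <- data.frame(lake_id = "L", layer = "epilimnion", top_m = 0,
                     bottom_m = 5, chl_ug_L = 10, phi_psii = 0.5,
                     par_umol_m2_s = 1e6)
  out <- gpp_profile(prof, p_max_per_chl = 1, daylength_hours = 10)
  expect_equal(out$gpp_o2_mg_m3_d, 50, tolerance = 1e-9) # tanh saturated
  expect_equal(out$gpp_c_mg_m3_d, 16, tolerance = 1e-9)
  # zero light or zero photochemistry mean zero production
  expect_equal(gpp_profile(dplyr::mutate(prof, par_umol_m2_s = 0)
                           )$gpp_c_mg_m3_d, 0)
  expect_equal(gpp_profile(dplyr::mutate(prof, phi_psii = 0)
                           )$gpp_c_mg_m3_d, 0)
  expect_error(gpp_profile(prof, model = "mystery"), "tanh_saturating")
  expect_error(gpp_profile(dplyr::mutate(prof, phi_psii = 2)), "phi_psii")
})

test_that("depth integration is unit-correct, additive and share-true", {
  expect_equal(depth_integrate(1000, 1)$areal_g_m2_d, 1)
  expect_equal(depth_integrate(c(0, 0), c(2, 3))$areal_g_m2_d, 0)
  expect_equal(depth_integrate(c(90, 10), c(1, 1))$share, c(0.9, 0.1))
  # splitting a layer leaves the areal total unchanged
  whole <- depth_integrate(c(400, 100), c(6, 4))$areal_g_m2_d
  split <- depth_integrate(c(400, 400, 100), c(2, 4, 4))$areal_g_m2_d
  expect_equal(split, whole, tolerance = 1e-12)
  expect_error(depth_integrate(c(1, 2), 1), "length")
  expect_error(depth_integrate(1, 0), "> 0")
})

test_that("rotifers contribute biomass but never secondary production", {
  zc <- dplyr::bind_rows(
    toy_zoo(species = "crust", group = "Copepoda", abundance = 10),
    toy_zoo(species = "rot", group = "Rotifera", abundance = 1000)
  )
  al <- toy_allometry(species = c("crust", "rot"),
                      group = c("Copepoda", "Rotifera"),
                      a = c(10, 10), b = c(0, 0))
  prof <- data.frame(lake_id = "L1", layer = "epilimnion", top_m = 0,
                     bottom_m = 5, chl_ug_L = 5, phi_psii = 0.5,
                     par_umol_m2_s = 300)
  bio <- sample_biomass(zc, al)
  prod <- compute_production(prof, bio)
  only_crust <- compute_production(prof, bio[bio$group != "Rotifera", ])
  expect_equal(prod$areal$sp_areal_gC_m2_d,
               only_crust$areal$sp_areal_gC_m2_d)
  expect_gt(prod$areal$sp_areal_gC_m2_d, 0)
})

test_that("eutrophic lakes concentrate production in the epilimnion", {
  sv <- generate_survey(class_config("eutrophic", 30, seed = 13))
  bio <- sample_biomass(sv$zoo_counts)
  prod <- compute_production(sv$profiles, bio)
  expect_gt(mean(prod$areal$epilimnion_gpp_share), 0.9)
  # shares always form a partition of the areal total
  shares <- tapply(prod$layers$gpp_share, prod$layers$lake_id, sum)
  expect_true(all(abs(shares - 1) < 1e-9))
})
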