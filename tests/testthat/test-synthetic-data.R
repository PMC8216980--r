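test_that("generation is reproducible and order-independent per lake", {
  s1 <- generate_survey(tiny_config(seed = 3))
  s2 <- generate_survey(tiny_config(seed = 3))
  expect_identical(lapply(s1, as.data.frame), lapply(s2, as.data.frame))

  s3 <- generate_survey(tiny_config(seed = 4))
  expect_false(identical(s1$lakes$chl_ug_L, s3$lakes$chl_ug_L))

  # a lake keeps its own draws when the survey grows around it
  big <- generate_survey(tiny_config(seed = 3, n = c(
    oligotrophic = 3, mesotrophic = 1, eutrophic = 1, dystrophic = 1)))
  shared <- intersect(s1$lakes$lake_id, big$lakes$lake_id)
  expect_equal(
    s1$lakes[match(shared, s1$lakes$lake_id), ],
    big$lakes[match(shared, big$lakes$lake_id), ]
  )
})

test_that("zero lakes per class yields an empty survey", {
  sv <- generate_survey(tiny_config(n = c(
    oligotrophic = 0, mesotrophic = 0, eutrophic = 0, dystrophic = 0)))
  expect_identical(nrow(sv$lakes), 0L)
  expect_identical(nrow(sv$profiles), 0L)
  expect_identical(nrow(sv$zoo_counts), 0L)
})

test_that("zero-sd configuration reproduces the configured means exactly", {
  sv <- generate_survey(degenerate_config())
  cfg <- degenerate_config()
  for (cl in trophic_classes()) {
    row <- sv$lakes[sv$lakes$true_class == cl, ]
    expect_identical(row$chl_ug_L, cfg$chl_mean_sd[[cl]][1])
    expect_identical(row$sdv_m, cfg$sdv_mean_sd[[cl]][1])
    expect_identical(row$tp_ug_L, cfg$tp_mean_sd[[cl]][1])
    expect_identical(row$ec_uS_cm, cfg$chemistry[[cl]]$ec[1])
  }
})

test_that("generate_zoo_sample honours degenerate and empty assemblages", {
  one <- tibble::tibble(species = "Daphnia cucullata", group = "Cladocera",
                        abund_mean = 5, abund_sd = 0, length_mean_mm = 1,
                        length_sd_mm = 0)
  zs <- generate_zoo_sample(one, "epilimnion", seed = 9)
  expect_identical(unique(zs$species), "Daphnia cucullata")
  expect_true(all(zs$abundance_ind_L == 5))
  expect_true(all(zs$length_mm == 1))
  expect_identical(nrow(zs), 10L) # ten measured individuals per species

  empty <- one[0, ]
  expect_identical(nrow(generate_zoo_sample(empty, "epilimnion", 1)), 0L)

  expect_identical(generate_zoo_sample(one, "epilimnion", seed = 7),
                   generate_zoo_sample(one, "epilimnion", seed = 7))

  bad <- dplyr::mutate(one, group = "Insecta")
  expect_error(generate_zoo_sample(bad, "epilimnion", 1), "unknown")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(n_lakes_per_class = c(oligotrophic = 1)),
               "n_lakes_per_class")
  cfg <- tiny_config()
  cfg$chl_mean_sd$dystrophic <- c(47.65, -1)
  expect_error(generate_survey(cfg), "chl_mean_sd")
  cfg <- tiny_config()
  cfg$depth_layers$eutrophic <- tibble::tibble(
    layer = c("epilimnion", "metalimnion"), top_m = c(0, 3),
    bottom_m = c(5, 8)) # overlapping
  expect_error(generate_survey(cfg), "depth_layers")
  cfg <- tiny_config()
  cfg$fa_profile_template$zoo <- c("16:0" = 0.6, "18:0" = 0.3)
  expect_error(generate_survey(cfg), "fa_profile_template")
  cfg <- tiny_config()
  cfg$chl_vertical_mode[["eutrophic"]] <- "surface-max"
  expect_error(generate_survey(cfg), "chl_vertical_mode")
})

test_that("chlorophyll maxima sit in the class-typical layer", {
  sv <- generate_survey(generator_config(seed = 11, n_lakes_per_class = c(
    oligotrophic = 40, mesotrophic = 40, eutrophic = 40, dystrophic = 0)))
  max_layer <- sv$profiles |>
    dplyr::group_by(lake_id) |>
    dplyr::summarise(ml = layer[which.max(chl_ug_L)], .groups = "drop") |>
    dplyr::inner_join(sv$lakes[, c("lake_id", "true_class")], by = "lake_id")
  frac_epi <- tapply(max_layer$ml == "epilimnion", max_layer$true_class,
                     mean)
  expect_gt(frac_epi[["eutrophic"]], 0.5)
  expect_gt(1 - frac_epi[["oligotrophic"]], 0.5)
  expect_gt(1 - frac_epi[["mesotrophic"]], 0.5)
})

test_that("PAR never increases with depth within a lake", {
  sv <- generate_survey(tiny_config(seed = 21, n = c(
    oligotrophic = 5, mesotrophic = 5, eutrophic = 5, dystrophic = 5)))
  by_lake <- split(sv$profiles, sv$profiles$lake_id)
  for (pr in by_lake) {
    pr <- pr[order(pr$top_m), ]
    expect_true(all(diff(pr$par_umol_m2_s) <= 0))
  }
})

test_that("class chemistry means converge to the configured values", {
  n <- 250
  cfg <- generator_config(seed = 31, n_lakes_per_class = c(
    oligotrophic = n, mesotrophic = n, eutrophic = n, dystrophic = n))
  sv <- generate_survey(cfg)
  for (cl in trophic_classes()) {
    chl <- sv$lakes$chl_ug_L[sv$lakes$true_class == cl]
    mu <- cfg$chl_mean_sd[[cl]][1]
    mc_tol <- 4 * cfg$chl_mean_sd[[cl]][2] / sqrt(n) # 4 MC standard errors
    expect_lt(abs(mean(chl) - mu), mc_tol)
    tp <- sv$lakes$tp_ug_L[sv$lakes$true_class == cl]
    expect_lt(abs(mean(tp) - cfg$tp_mean_sd[[cl]][1]),
              4 * cfg$tp_mean_sd[[cl]][2] / sqrt(n))
  }
})

test_that("seston C:P is high in dystrophic and oligotrophic lakes", {
  sv <- generate_survey(generator_config(seed = 41, n_lakes_per_class = c(
    oligotrophic = 40, mesotrophic = 40, eutrophic = 40, dystrophic = 40)))
  cp <- sv$composition |>
    dplyr::filter(compartment == "seston") |>
    dplyr::inner_join(sv$lakes[, c("lake_id", "true_class")],
                      by = "lake_id") |>
    dplyr::group_by(true_class) |>
    dplyr::summarise(cp = mean(c_pct / p_pct), .groups = "drop")
  cp <- setNames(cp$cp, cp$true_class)
  expect_gt(cp[["dystrophic"]], cp[["mesotrophic"]])
  expect_gt(cp[["dystrophic"]], cp[["eutrophic"]])
  expect_gt(cp[["oligotrophic"]], cp[["mesotrophic"]])
  expect_gt(cp[["oligotrophic"]], cp[["eutrophic"]])
})

test_that("surveys satisfy their structural invariants", {
  sv <- generate_survey(tiny_config(seed = 55, n = c(
    oligotrophic = 2, mesotrophic = 2, eutrophic = 2, dystrophic = 2)))
  # every zoo sample references an existing layer
  keys <- paste(sv$profiles$lake_id, sv$profiles$layer)
  expect_true(all(paste(sv$zoo_counts$lake_id, sv$zoo_counts$layer) %in%
                    keys))
  # fatty-acid percentages sum to 100 per lake and compartment
  sums <- sv$fatty_acids |>
    dplyr::group_by(lake_id, compartment) |>
    dplyr::summarise(s = sum(pct_total), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
  # compositions are valid percentages
  expect_true(all(sv$composition$c_pct + sv$composition$n_pct +
                    sv$composition$p_pct < 100))
  # dystrophic lakes carry the dystrophic assemblage dominants
  dys_sp <- sv$zoo_counts$species[
    sv$zoo_counts$lake_id %in%
      sv$lakes$lake_id[sv$lakes$true_class == "dystrophic"]]
  expect_true(all(c("Asplanchna priodonta", "Ceriodaphnia quadrangula",
                    "Eudiaptomus gracilis") %in% dys_sp))
})
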