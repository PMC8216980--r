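test_that("substance production converts through compartment ratios", {
  # carbon is the identity
  expect_equal(substance_production(100, "C"), 100)
  expect_equal(substance_production(0, "P", c_pct = 47.7, p_pct = 0.9), 0)
  # phosphorus production from typical consumer stoichiometry
  expect_equal(substance_production(100, "P", c_pct = 47.7, p_pct = 0.9),
               100 * 0.9 / 47.7, tolerance = 1e-12)
  expect_equal(round(substance_production(100, "P", c_pct = 47.7,
                                          p_pct = 0.9), 3), 1.887)
  expect_equal(substance_production(100, "N", c_pct = 47.7, n_pct = 9.9),
               100 * 9.9 / 47.7, tolerance = 1e-12)
  expect_equal(substance_production(50, "omega3", omega3_per_c = 0.01),
               0.5)
  # the naive %DW reading stays available behind the flag
  expect_equal(substance_production(100, "P", p_pct = 0.9,
                                    mode = "pct_dw"), 0.9)
  expect_error(substance_production(10, "P", c_pct = 47.7), "p_pct")
})

test_that("transfer efficiency is a flagged percentage ratio", {
  te <- transfer_efficiency(6.55, 100)
  expect_equal(te$tte_pct, 6.55)
  expect_false(te$artefact)
  # boundary: 100% is not an artefact; the flag is strictly > 100
  expect_false(transfer_efficiency(10, 10)$artefact)
  expect_true(transfer_efficiency(10.1, 10)$artefact)
  expect_equal(transfer_efficiency(0, 10)$tte_pct, 0)
  expect_true(is.na(transfer_efficiency(5, 0)$tte_pct))
  # scale invariance
  expect_equal(transfer_efficiency(3 * 7, 3 * 50)$tte_pct,
               transfer_efficiency(7, 50)$tte_pct)
  expect_error(transfer_efficiency(-1, 10), ">= 0")
})

test_that("fold ranges reproduce the printed between-lake contrasts", {
  carbon <- fold_range(c(0.34, 6.2, 25.8))
  expect_equal(carbon$fold, 25.8 / 0.34, tolerance = 1e-12)
  expect_equal(carbon$fold_rounded, 76)
  phosphorus <- fold_range(c(0.57, 71.57))
  expect_equal(phosphorus$fold, 71.57 / 0.57, tolerance = 1e-12)
  expect_equal(phosphorus$fold_rounded, 126) # unrounded extremes give 125.6
  expect_equal(fold_range(5)$fold, 1)
  # permutation invariance and monotonicity under enlargement
  expect_equal(fold_range(c(25.8, 0.34))$fold, carbon$fold)
  expect_gte(fold_range(c(0.34, 6.2, 25.8, 30))$fold, carbon$fold)
  expect_warning(f <- fold_range(c(0, 1, 10)), "non-positive")
  expect_equal(f$fold, 10)
  expect_error(suppressWarnings(fold_range(c(0, 0))), "positive value")
})

test_that("class summaries exclude artefacts but keep their count", {
  tte <- tibble::tibble(
    lake_id = c("a", "b", "c"), substance = "omega3",
    producer_mg_m2_d = 1, consumer_mg_m2_d = 1,
    tte_pct = c(20, 30, 150), artefact = c(FALSE, FALSE, TRUE)
  )
  cls <- tibble::tibble(lake_id = c("a", "b", "c"),
                        trophic_class = "oligotrophic")
  sm <- summarize_tte(tte, cls)
  row <- sm[sm$trophic_class == "oligotrophic", ]
  expect_equal(row$mean, 25)
  expect_equal(row$n_artefact, 1L)
  # identical values collapse to zero spread
  tte2 <- dplyr::mutate(tte, tte_pct = 12, artefact = FALSE)
  expect_equal(summarize_tte(tte2, cls)$sd[1], 0)
  expect_error(summarize_tte(tte, cls[1:2, ]), "no class")
})

test_that("TTE ratios collapse to compartment stoichiometry", {
  sv <- generate_survey(tiny_config(seed = 19, n = c(
    oligotrophic = 2, mesotrophic = 2, eutrophic = 2, dystrophic = 2)))
  bio <- sample_biomass(sv$zoo_counts)
  prod <- compute_production(sv$profiles, bio)
  tte <- compute_tte(prod$areal, sv$composition, sv$fatty_acids, bio)
  wide <- tidyr::pivot_wider(tte[, c("lake_id", "substance", "tte_pct")],
                             names_from = "substance",
                             values_from = "tte_pct")
  comp <- tidyr::pivot_wider(
    sv$composition[, c("lake_id", "compartment", "c_pct", "n_pct",
                       "p_pct")],
    names_from = "compartment", values_from = c("c_pct", "n_pct", "p_pct")
  )
  j <- dplyr::inner_join(wide, comp, by = "lake_id")
  # exact algebraic identity: TTE_P / TTE_C = (P:C)_zoo / (P:C)_seston
  expect_equal(j$P / j$C,
               (j$p_pct_zooplankton / j$c_pct_zooplankton) /
                 (j$p_pct_seston / j$c_pct_seston), tolerance = 1e-9)
  expect_equal(j$N / j$C,
               (j$n_pct_zooplankton / j$c_pct_zooplankton) /
                 (j$n_pct_seston / j$c_pct_seston), tolerance = 1e-9)
})

test_that("compute_tte demands both compartment compositions", {
  sv <- generate_survey(tiny_config(seed = 23, n = c(
    oligotrophic = 1, mesotrophic = 0, eutrophic = 0, dystrophic = 0)))
  bio <- sample_biomass(sv$zoo_counts)
  prod <- compute_production(sv$profiles, bio)
  lopsided <- sv$composition[sv$composition$compartment == "seston", ]
  expect_error(compute_tte(prod$areal, lopsided, sv$fatty_acids, bio),
               "missing compartment")
})
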