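#' Per-substance production from carbon production
#'
#' Converts carbon-unit production into production of another substance
#' using the composition of the producing compartment. Production is
#' already in carbon units, so for nitrogen and phosphorus the default
#' ("element_ratio") multiplies by the compartment's element-to-carbon
#' ratio (e.g. `p_pct / c_pct`); for omega-3 PUFA it multiplies by the
#' compartment's omega-3 mass per unit carbon. The naive reading
#' (multiplying carbon production by the element's % of dry weight) is
#' retained behind `mode = "pct_dw"` for sensitivity analysis — it
#' double-counts the carbon basis and is not the default.
#'
#' @param carbon_production Production in carbon units, >= 0 (any unit;
#'   the result shares it).
#' @param substance One of "C", "N", "P", "omega3".
#' @param c_pct,n_pct,p_pct Elemental content of the compartment (% DW);
#'   needed for N and P.
#' @param omega3_per_c Omega-3 mass per unit carbon mass of the compartment
#'   (dimensionless); needed for omega3.
#' @param mode "element_ratio" (default) or "pct_dw".
#' @return Substance production in the unit of `carbon_production`.
#' @examples
#' substance_production(100, "P", c_pct = 47.7, p_pct = 0.9) # 1.887
#' @export
substance_production <- function(carbon_production, substance,
                                 c_pct = NULL, n_pct = NULL, p_pct = NULL,
                                 omega3_per_c = NULL,
                                 mode = c("element_ratio", "pct_dw")) {
  mode <- match.arg(mode)
  if (any(carbon_production < 0, na.rm = TRUE)) {
    abort("substance_production(): carbon production must be >= 0")
  }
  substance <- match.arg(substance, c("C", "N", "P", "omega3"))
  req <- function(x, what) {
    if (is.null(x) || all(is.na(x))) {
      abort(paste0("substance_production(): ", what,
                   " required for substance ", substance))
    }
    x
  }
  switch(substance,
    C = carbon_production,
    N = {
      n <- req(n_pct, "n_pct")
      if (mode == "element_ratio") {
        carbon_production * n / req(c_pct, "c_pct")
      } else {
        carbon_production * n / 100
      }
    },
    P = {
      p <- req(p_pct, "p_pct")
      if (mode == "element_ratio") {
        carbon_production * p / req(c_pct, "c_pct")
      } else {
        carbon_production * p / 100
      }
    },
    omega3 = carbon_production * req(omega3_per_c, "omega3_per_c")
  )
}

#' Trophic transfer efficiency
#'
#' \deqn{TTE = 100 \times consumer\ production / producer\ production}
#' with an artefact flag for values above 100% (impossible efficiencies,
#' in practice caused by unreliable trace measurements in the producer
#' compartment). A zero producer production makes the ratio undefined and
#' is reported as NA, never infinity.
#'
#' @param consumer_production,producer_production Same-unit production
#'   rates, >= 0.
#' @return Tibble with `tte_pct` and `artefact` (TRUE iff tte_pct > 100).
#' @examples
#' transfer_efficiency(6.55, 100) # 6.55 %
#' @export
transfer_efficiency <- function(consumer_production, producer_production) {
  if (any(consumer_production < 0, na.rm = TRUE) ||
      any(producer_production < 0, na.rm = TRUE)) {
    abort("transfer_efficiency(): productions must be >= 0")
  }
  tte <- ifelse(is.na(producer_production) | producer_production == 0,
                NA_real_,
                100 * consumer_production / producer_production)
  tibble::tibble(tte_pct = tte, artefact = !is.na(tte) & tte > 100)
}

#' Fold range of transfer efficiencies
#'
#' The max/min ratio across lakes, the headline between-lake contrast.
#' Artefacts (> 100%) must be excluded by the caller beforehand;
#' non-positive values are dropped with a warning before the ratio.
#'
#' @param values TTE values (%), at least one positive.
#' @return Tibble with `min`, `max`, `fold` (raw) and `fold_rounded`
#'   (nearest integer; printed fold values are conventionally rounded).
#' @examples
#' fold_range(c(0.34, 6.2, 25.8))$fold_rounded # 76
#' @export
fold_range <- function(values) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) {
    warn("fold_range(): dropping non-positive values before the ratio")
    values <- values[values > 0]
  }
  if (length(values) == 0) {
    abort("fold_range(): need at least one positive value")
  }
  tibble::tibble(min = min(values), max = max(values),
                 fold = max(values) / min(values),
                 fold_rounded = round(max(values) / min(values)))
}

#' Per-lake, per-substance transfer efficiencies for a survey
#'
#' Runs the substance-transfer stage on pipeline outputs: takes each lake's
#' areal GPP (producer, carbon units) and SP (consumer, carbon units),
#' derives N, P and omega-3 production from the seston and zooplankton
#' compositions, and computes the four efficiencies with artefact flags.
#'
#' Omega-3 content enters as mass per unit carbon of each compartment:
#' seston omega-3 concentration (ug/L) over seston carbon concentration
#' (`c_ug_L` in the composition table), and zooplankton omega-3
#' concentration over zooplankton carbon concentration (taken from
#' `c_ug_L` when present, otherwise dry biomass x carbon content).
#'
#' @param areal Per-lake areal production (`areal` element of
#'   [compute_production()]).
#' @param composition,fatty_acids Survey composition tables (see
#'   [composition_summary()]).
#' @param biomass Optional [sample_biomass()] output, used to reconstruct
#'   zooplankton carbon concentration when `c_ug_L` is absent.
#' @param mode Substance-production mode, see [substance_production()].
#' @return Tibble with one row per (lake_id, substance):
#'   `producer_mg_m2_d`, `consumer_mg_m2_d`, `tte_pct`, `artefact`.
#' @export
compute_tte <- function(areal, composition, fatty_acids, biomass = NULL,
                        mode = "element_ratio") {
  comp <- composition_summary(composition, fatty_acids)
  seston <- dplyr::filter(comp, .data$compartment == "seston")
  zoo <- dplyr::filter(comp, .data$compartment == "zooplankton")
  miss <- setdiff(areal$lake_id, intersect(seston$lake_id, zoo$lake_id))
  if (length(miss) > 0) {
    abort(paste0("compute_tte(): missing compartment composition for ",
                 "lake(s): ", paste(miss, collapse = ", ")))
  }

  # zooplankton carbon concentration (ug C/L) for the omega-3 basis
  if (!is.null(biomass)) {
    zoo_c <- biomass |>
      dplyr::group_by(.data$lake_id) |>
      dplyr::summarise(dw_ug_L = sum(.data$biomass_dw_ug_L),
                       .groups = "drop")
    zoo <- dplyr::left_join(zoo, zoo_c, by = "lake_id") |>
      dplyr::mutate(c_ug_L = dplyr::coalesce(
        .data$c_ug_L, .data$dw_ug_L * .data$c_pct / 100
      ))
  }

  tbl <- areal |>
    dplyr::transmute(
      lake_id = .data$lake_id,
      producer_c = .data$gpp_areal_gC_m2_d * 1000, # mgC m^-2 d^-1
      consumer_c = .data$sp_areal_gC_m2_d * 1000
    ) |>
    dplyr::left_join(
      seston |>
        dplyr::transmute(lake_id = .data$lake_id, s_c = .data$c_pct,
                         s_n = .data$n_pct, s_p = .data$p_pct,
                         s_om_per_c = .data$omega3_ug_L / .data$c_ug_L),
      by = "lake_id"
    ) |>
    dplyr::left_join(
      zoo |>
        dplyr::transmute(lake_id = .data$lake_id, z_c = .data$c_pct,
                         z_n = .data$n_pct, z_p = .data$p_pct,
                         z_om_per_c = .data$omega3_ug_L / .data$c_ug_L),
      by = "lake_id"
    )

  out <- purrr::map(c("C", "N", "P", "omega3"), function(sub) {
    prod <- substance_production(tbl$producer_c, sub, c_pct = tbl$s_c,
                                 n_pct = tbl$s_n, p_pct = tbl$s_p,
                                 omega3_per_c = tbl$s_om_per_c, mode = mode)
    cons <- substance_production(tbl$consumer_c, sub, c_pct = tbl$z_c,
                                 n_pct = tbl$z_n, p_pct = tbl$z_p,
                                 omega3_per_c = tbl$z_om_per_c, mode = mode)
    dplyr::bind_cols(
      tibble::tibble(lake_id = tbl$lake_id, substance = sub,
                     producer_mg_m2_d = prod, consumer_mg_m2_d = cons),
      transfer_efficiency(cons, prod)
    )
  })
  dplyr::bind_rows(out)
}

#' Summarise transfer efficiencies by trophic class
#'
#' Mean and sd of TTE per (class, substance) and overall per substance.
#' Artefacts (> 100%) are excluded from all summary statistics (the
#' convention used for the omega-3 means, where trace-level producer
#' measurements generate impossible efficiencies) but are counted in
#' `n_artefact`; raw per-lake values keep their flags in the TTE table.
#'
#' @param tte Output of [compute_tte()].
#' @param classes Data frame mapping `lake_id` to a class column (either
#'   `trophic_class` from [assess_trophic()] or `true_class` from the
#'   generator).
#' @param class_col Name of the class column in `classes`.
#' @return Tibble per (class, substance) with `n`, `n_artefact`, `mean`,
#'   `sd`; class "all" rows hold the overall summaries.
#' @export
summarize_tte <- function(tte, classes, class_col = "trophic_class") {
  if (!class_col %in% names(classes)) {
    abort(paste0("summarize_tte(): column '", class_col,
                 "' not found in classes"))
  }
  joined <- tte |>
    dplyr::inner_join(
      dplyr::select(classes, "lake_id", cls = dplyr::all_of(class_col)),
      by = "lake_id"
    )
  if (nrow(joined) < nrow(tte)) {
    abort("summarize_tte(): some lakes have no class assignment")
  }
  summ <- function(df) {
    df |>
      dplyr::summarise(
        n = sum(!is.na(.data$tte_pct)),
        n_artefact = sum(.data$artefact, na.rm = TRUE),
        mean = mean(.data$tte_pct[!.data$artefact], na.rm = TRUE),
        sd = sd(.data$tte_pct[!.data$artefact], na.rm = TRUE),
        .groups = "drop"
      )
  }
  by_class <- joined |>
    dplyr::group_by(trophic_class = .data$cls, .data$substance) |>
    summ()
  overall <- joined |>
    dplyr::group_by(.data$substance) |>
    summ() |>
    dplyr::mutate(trophic_class = "all", .before = 1)
  dplyr::bind_rows(by_class, overall)
}
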