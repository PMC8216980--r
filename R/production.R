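#' Conversion constants for production calculations
#'
#' Bundles the fixed unit conversions used throughout the production module:
#' oxygen-based primary production to carbon (0.32 gC per gO2), zooplankton
#' dry weight to carbon (1/2.3 gC per gDW) and wet weight to dry weight
#' (configurable, default 0.10).
#'
#' @param o2_to_c gC per gO2, default 0.32.
#' @param dw_to_c gC per g dry weight, default 1/2.3.
#' @param ww_to_dw g dry weight per g wet weight, default 0.10.
#' @return Named list of the three constants.
#' @export
conversion_constants <- function(o2_to_c = 0.32, dw_to_c = 1 / 2.3,
                                 ww_to_dw = 0.10) {
  if (o2_to_c <= 0 || dw_to_c <= 0 || ww_to_dw <= 0) {
    abort("conversion_constants(): all constants must be > 0")
  }
  list(o2_to_c = o2_to_c, dw_to_c = dw_to_c, ww_to_dw = ww_to_dw)
}

#' Crustacean secondary production regression
#'
#' The allometric daily-production regression for crustacean zooplankton,
#' \deqn{SP = 10^{(-0.23 \log_{10} M - 0.73)} \cdot 1.12 \cdot M \cdot N
#'        = 1.12 \cdot 10^{-0.73} \cdot M^{0.77} \cdot N,}
#' where `M` is mean individual dry weight (ug) and `N` abundance (ind/L);
#' SP is in ug DW per litre per day. The log is base 10 by default (the
#' convention of the source regression); `log_base` is exposed for
#' sensitivity analysis only.
#'
#' @param M Mean individual dry weight, ug, > 0 (where N > 0).
#' @param N Abundance, ind/L, >= 0.
#' @param log_base Base of the log in the exponent (default 10).
#' @return SP in ug DW L^-1 day^-1.
#' @examples
#' secondary_production(1, 1) # 1.12 * 10^-0.73 = 0.2086
#' @export
secondary_production <- function(M, N, log_base = 10) {
  tmp <- cbind(M = M, N = N) # recycles & checks lengths
  M <- tmp[, "M"]; N <- tmp[, "N"]
  if (any(N < 0)) abort("secondary_production(): N must be >= 0")
  if (any(N > 0 & M <= 0)) {
    abort("secondary_production(): M must be > 0 where N > 0")
  }
  res <- numeric(length(M))
  pos <- N > 0
  res[pos] <- 10^(-0.23 * log(M[pos], base = log_base) - 0.73) * 1.12 *
    M[pos] * N[pos]
  res
}

#' Dry weight to carbon
#'
#' @param dw Dry mass (any unit), >= 0.
#' @param constants See [conversion_constants()].
#' @return Carbon mass in the same unit: `dw * dw_to_c` (default dw / 2.3).
#' @export
dw_to_carbon <- function(dw, constants = conversion_constants()) {
  if (any(dw < 0)) abort("dw_to_carbon(): dry weight must be >= 0")
  dw * constants$dw_to_c
}

#' Oxygen-based GPP to carbon
#'
#' @param gpp_o2 Gross primary production in O2 units, >= 0.
#' @param constants See [conversion_constants()].
#' @return GPP in carbon units: `gpp_o2 * o2_to_c` (default x 0.32).
#' @export
gpp_o2_to_carbon <- function(gpp_o2, constants = conversion_constants()) {
  if (any(gpp_o2 < 0)) abort("gpp_o2_to_carbon(): GPP must be >= 0")
  gpp_o2 * constants$o2_to_c
}

# Registry of light-response models for volumetric oxygen production.
# Each takes the profile columns plus parameters and returns
# mg O2 m^-3 day^-1. The fluorometric (DCMU) field formula is proprietary
# to its source; this pluggable interface isolates the choice.
light_response_registry <- function() {
  list(
    tanh_saturating = function(chl, phi_psii, par, p_max_per_chl, par_sat,
                               daylength_hours) {
      p_max_per_chl * chl * phi_psii * tanh(par / par_sat) * daylength_hours
    },
    linear = function(chl, phi_psii, par, p_max_per_chl, par_sat,
                      daylength_hours) {
      p_max_per_chl * chl * phi_psii * pmin(par / par_sat, 1) *
        daylength_hours
    }
  )
}

#' Registered light-response model names
#' @return Character vector of model names accepted by [gpp_profile()].
#' @export
light_response_models <- function() names(light_response_registry())

#' Per-layer gross primary production in carbon units
#'
#' Applies a saturating light-response model to each layer's chlorophyll,
#' PSII photochemical activity (DCMU-type phi) and PAR:
#' \deqn{GPP_{O_2}(z) = P^{max}_{chl} \cdot chl(z) \cdot \phi_{PSII}(z)
#'   \cdot \tanh(PAR(z)/PAR_{sat}) \cdot daylength}
#' then converts to carbon with the 0.32 gC/gO2 factor. GPP is zero
#' wherever chlorophyll, phi or PAR is zero.
#'
#' @param profiles Data frame with columns `lake_id`, `layer`, `top_m`,
#'   `bottom_m`, `chl_ug_L`, `phi_psii`, `par_umol_m2_s`.
#' @param model Registered model name, see [light_response_models()].
#' @param p_max_per_chl Chlorophyll-specific maximum photosynthetic rate,
#'   mg O2 (mg chl)^-1 h^-1 expressed per ug chl/L of water (default 4, in
#'   the usual range for summer assemblages).
#' @param par_sat Saturation irradiance, umol photons m^-2 s^-1 (default 180).
#' @param daylength_hours Photoperiod, hours (default 16, mid-summer
#'   temperate).
#' @param constants See [conversion_constants()].
#' @return Input tibble with `gpp_o2_mg_m3_d` and `gpp_c_mg_m3_d` appended.
#' @export
gpp_profile <- function(profiles, model = "tanh_saturating",
                        p_max_per_chl = 4, par_sat = 180,
                        daylength_hours = 16,
                        constants = conversion_constants()) {
  reg <- light_response_registry()
  if (!model %in% names(reg)) {
    abort(paste0("gpp_profile(): unknown light-response model '", model,
                 "'; registered: ", paste(names(reg), collapse = ", ")))
  }
  need <- c("lake_id", "layer", "top_m", "bottom_m", "chl_ug_L", "phi_psii",
            "par_umol_m2_s")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    abort(paste0("gpp_profile(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(profiles$bottom_m <= profiles$top_m)) {
    abort("gpp_profile(): layer bottom must be deeper than top")
  }
  if (any(profiles$phi_psii < 0 | profiles$phi_psii > 1)) {
    abort("gpp_profile(): phi_psii must be in [0, 1]")
  }
  f <- reg[[model]]
  dplyr::as_tibble(profiles) |>
    dplyr::mutate(
      gpp_o2_mg_m3_d = f(.data$chl_ug_L, .data$phi_psii,
                         .data$par_umol_m2_s, p_max_per_chl, par_sat,
                         daylength_hours),
      gpp_c_mg_m3_d = gpp_o2_to_carbon(.data$gpp_o2_mg_m3_d, constants)
    )
}

#' Depth-integrate a volumetric profile
#'
#' Thickness-weighted rectangular integration of per-layer volumetric rates
#' (values are layer composites, not point measurements):
#' \deqn{areal = \sum_i v_i \cdot \Delta z_i / 1000}
#' converting mg m^-3 day^-1 to g m^-2 day^-1. Also returns each layer's
#' share of the areal total.
#'
#' @param values Volumetric values, mg m^-3 day^-1.
#' @param thickness_m Layer thicknesses, m, > 0.
#' @return List with `areal_g_m2_d` and `share` (per-layer fractions;
#'   NA when the total is zero).
#' @export
depth_integrate <- function(values, thickness_m) {
  if (length(values) != length(thickness_m)) {
    abort("depth_integrate(): values and thicknesses differ in length")
  }
  if (any(thickness_m <= 0)) {
    abort("depth_integrate(): thicknesses must be > 0")
  }
  contrib <- values * thickness_m / 1000
  total <- sum(contrib)
  share <- if (total > 0) contrib / total else rep(NA_real_, length(contrib))
  list(areal_g_m2_d = total, share = share)
}

#' Full production profile: GPP and SP per layer and areal
#'
#' Runs the whole production stage for a survey: per-layer volumetric GPP
#' (light-response model on the profiles) and crustacean SP (allometric
#' regression per species on the biomass table, rotifers excluded), then
#' depth-integrates both and reports the epilimnion share of GPP.
#' SP in ug DW L^-1 day^-1 equals mg DW m^-3 day^-1, so both rates share
#' the volumetric unit before carbon conversion.
#'
#' @param profiles Layer profile table, see [gpp_profile()].
#' @param biomass Per-species biomass table from [sample_biomass()].
#' @param constants See [conversion_constants()].
#' @inheritParams gpp_profile
#' @return List of two tibbles: `layers` (per lake x layer volumetric
#'   GPP/SP in mgC m^-3 d^-1 plus shares) and `areal` (per lake areal GPP
#'   and SP in gC m^-2 d^-1 and `epilimnion_gpp_share`).
#' @export
compute_production <- function(profiles, biomass,
                               model = "tanh_saturating",
                               p_max_per_chl = 4, par_sat = 180,
                               daylength_hours = 16,
                               constants = conversion_constants()) {
  gpp <- gpp_profile(profiles, model = model,
                     p_max_per_chl = p_max_per_chl, par_sat = par_sat,
                     daylength_hours = daylength_hours,
                     constants = constants)

  # SP per crustacean species from its own mean dry mass, then summed
  sp_layer <- biomass |>
    dplyr::filter(.data$group %in% c("Cladocera", "Copepoda")) |>
    dplyr::mutate(sp_dw = secondary_production(.data$mean_dw_ug,
                                               .data$abundance_ind_L)) |>
    dplyr::group_by(.data$lake_id, .data$layer) |>
    dplyr::summarise(sp_dw_mg_m3_d = sum(.data$sp_dw), .groups = "drop") |>
    dplyr::mutate(sp_c_mg_m3_d = dw_to_carbon(.data$sp_dw_mg_m3_d,
                                              constants))

  layers <- gpp |>
    dplyr::left_join(sp_layer, by = c("lake_id", "layer")) |>
    dplyr::mutate(
      sp_dw_mg_m3_d = dplyr::coalesce(.data$sp_dw_mg_m3_d, 0),
      sp_c_mg_m3_d = dplyr::coalesce(.data$sp_c_mg_m3_d, 0),
      thickness_m = .data$bottom_m - .data$top_m
    )

  areal <- layers |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(
      gpp_areal_gC_m2_d = depth_integrate(.data$gpp_c_mg_m3_d,
                                          .data$thickness_m)$areal_g_m2_d,
      sp_areal_gC_m2_d = depth_integrate(.data$sp_c_mg_m3_d,
                                         .data$thickness_m)$areal_g_m2_d,
      epilimnion_gpp_share = {
        sh <- depth_integrate(.data$gpp_c_mg_m3_d, .data$thickness_m)$share
        idx <- which(.data$layer == "epilimnion")
        if (length(idx) == 1) sh[idx] else NA_real_
      },
      .groups = "drop"
    )

  layers <- layers |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::mutate(
      gpp_share = depth_integrate(.data$gpp_c_mg_m3_d,
                                  .data$thickness_m)$share
    ) |>
    dplyr::ungroup()

  list(layers = layers, areal = areal)
}
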