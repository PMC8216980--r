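#' Default length-weight allometry table
#'
#' Power-law coefficients `mass_ug = a * length_mm^b` per species, wet-mass
#' basis. Crustacean coefficients are of the kind tabulated in the standard
#' length-weight compilations for European lake zooplankton; rotifer values
#' follow volume-based length-weight relationships. They are
#' literature-plausible defaults for the species pools the synthetic
#' generator uses: for any real survey supply your own table (same columns)
#' with the coefficients actually applicable to your taxa.
#'
#' @return A tibble with columns `species`, `group`, `a`, `b`,
#'   `output_basis` (all "wet_ug") and `source`.
#' @export
default_allometry <- function() {
  if (is.null(.limnotte_cache$allometry)) {
    path <- system.file("extdata", "allometry.csv", package = "limnotte")
    .limnotte_cache$allometry <-
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  .limnotte_cache$allometry
}

.limnotte_cache <- new.env(parent = emptyenv())

#' Individual body mass from length
#'
#' Evaluates the allometric power law `mass = a * length^b`.
#'
#' @param length_mm Body length(s), mm, > 0.
#' @param a,b Allometric coefficient and exponent.
#' @return Mass in the table's output basis (ug).
#' @examples
#' individual_mass(2, a = 0.05, b = 3) # 0.4
#' @export
individual_mass <- function(length_mm, a, b) {
  if (any(!is.na(length_mm) & length_mm <= 0)) {
    abort("individual_mass(): lengths must be > 0")
  }
  if (any(a <= 0)) abort("individual_mass(): coefficient a must be > 0")
  if (any(b < 0 | b > 5)) {
    abort("individual_mass(): exponent b outside plausible range [0, 5]")
  }
  a * length_mm^b
}

#' Zooplankton biomass per lake, layer and species
#'
#' Converts count-and-length records to biomass. For each (lake, layer,
#' species) the mean individual mass is the mean of the per-individual
#' masses (each measured length pushed through the power law, not the mass
#' of the mean length), and
#' \deqn{biomass\ (mg/L) = mean\ mass\ (\mu g) \times abundance\ (ind/L) / 1000.}
#' Dry mass is derived from wet mass with a single configurable fraction.
#'
#' @param zoo_counts Long table with columns `lake_id`, `layer`, `species`,
#'   `group` (Cladocera/Copepoda/Rotifera), `abundance_ind_L` and
#'   `length_mm` (one row per measured individual; abundance repeated).
#' @param allometry Parameter table as in [default_allometry()].
#' @param ww_to_dw Wet-to-dry mass fraction (default 0.10).
#' @return A tibble with one row per (lake_id, layer, species): `group`,
#'   `abundance_ind_L`, `mean_mass_ug` (wet), `mean_dw_ug` (dry),
#'   `biomass_mg_L` (wet), `biomass_dw_ug_L` (dry, ug/L) and the species'
#'   `dominance` fraction of the layer total.
#' @examples
#' zc <- data.frame(lake_id = "L1", layer = "epilimnion", species = "sp",
#'                  group = "Cladocera", abundance_ind_L = 100,
#'                  length_mm = 1)
#' al <- data.frame(species = "sp", group = "Cladocera", a = 10, b = 0,
#'                  output_basis = "wet_ug", source = "toy")
#' sample_biomass(zc, al) # 1 mg/L
#' @export
sample_biomass <- function(zoo_counts, allometry = default_allometry(),
                           ww_to_dw = 0.10) {
  stopifnot(is.data.frame(zoo_counts))
  need <- c("lake_id", "layer", "species", "group", "abundance_ind_L",
            "length_mm")
  miss <- setdiff(need, names(zoo_counts))
  if (length(miss) > 0) {
    abort(paste0("sample_biomass(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ok_groups <- c("Cladocera", "Copepoda", "Rotifera")
  bad_grp <- setdiff(unique(zoo_counts$group), ok_groups)
  if (length(bad_grp) > 0) {
    abort(paste0("sample_biomass(): unknown zooplankton group(s): ",
                 paste(bad_grp, collapse = ", ")))
  }
  if (any(zoo_counts$abundance_ind_L < 0)) {
    abort("sample_biomass(): abundances must be >= 0")
  }
  unknown <- setdiff(unique(zoo_counts$species), allometry$species)
  if (length(unknown) > 0) {
    abort(paste0("sample_biomass(): no allometric parameters for species: ",
                 paste(unknown, collapse = ", ")))
  }
  no_len <- zoo_counts |>
    dplyr::group_by(.data$lake_id, .data$layer, .data$species) |>
    dplyr::summarise(
      n_len = sum(!is.na(.data$length_mm)),
      ab = .data$abundance_ind_L[1], .groups = "drop"
    ) |>
    dplyr::filter(.data$n_len == 0, .data$ab > 0)
  if (nrow(no_len) > 0) {
    abort(paste0("sample_biomass(): species with abundance > 0 but no ",
                 "measured lengths: ",
                 paste(unique(no_len$species), collapse = ", ")))
  }

  out <- zoo_counts |>
    dplyr::inner_join(allometry[, c("species", "a", "b")], by = "species") |>
    dplyr::mutate(mass_ug = individual_mass(.data$length_mm, .data$a, .data$b)) |>
    dplyr::group_by(.data$lake_id, .data$layer, .data$species,
                    .data$group) |>
    dplyr::summarise(
      abundance_ind_L = .data$abundance_ind_L[1],
      mean_mass_ug = mean(.data$mass_ug, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_mass_ug = ifelse(is.nan(.data$mean_mass_ug), 0, .data$mean_mass_ug),
      mean_dw_ug = .data$mean_mass_ug * ww_to_dw,
      biomass_mg_L = .data$mean_mass_ug * .data$abundance_ind_L / 1000,
      biomass_dw_ug_L = .data$mean_dw_ug * .data$abundance_ind_L
    ) |>
    dplyr::group_by(.data$lake_id, .data$layer) |>
    dplyr::mutate(
      dominance = if (sum(.data$biomass_mg_L) > 0) {
        .data$biomass_mg_L / sum(.data$biomass_mg_L)
      } else {
        rep(NA_real_, dplyr::n())
      }
    ) |>
    dplyr::ungroup()
  out
}

#' Layer and group biomass totals
#'
#' @param biomass Output of [sample_biomass()].
#' @return Tibble with one row per (lake_id, layer, group) and the wet and
#'   dry biomass totals.
#' @export
biomass_by_group <- function(biomass) {
  biomass |>
    dplyr::group_by(.data$lake_id, .data$layer, .data$group) |>
    dplyr::summarise(
      biomass_mg_L = sum(.data$biomass_mg_L),
      biomass_dw_ug_L = sum(.data$biomass_dw_ug_L),
      .groups = "drop"
    )
}
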