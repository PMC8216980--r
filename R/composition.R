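#' Normalize a fatty-acid name
#'
#' Maps the common spelling variants of shorthand fatty-acid names onto one
#' canonical form: lower case, the omega suffix written `n-x` (accepting
#' "n-3", "n3", "w3", and the Greek omega), iso/anteiso prefixes kept as
#' `i`/`a`, and sum markers kept with their `sum` prefix spelled `s`
#' (e.g. `s14:1` for a summed 14:1 pool).
#'
#' @param name Character vector of FA names (e.g. "18:3n-3", "i15:0",
#'   "22:6N3", "18:3w3").
#' @return Canonical names.
#' @examples
#' normalize_fa_name(c("18:3w3", "22:6N-3", "I15:0"))
#' @export
normalize_fa_name <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("ω", "n", x)       # omega
  x <- gsub("Σ|sum|∑", "s", x) # sigma / "sum" prefix
  x <- gsub("w(\\d)", "n-\\1", x)
  x <- gsub("n-?(\\d)", "n-\\1", x)
  x <- gsub("\\s+", "", x)
  x
}

#' The six omega-3 acids summed for the PUFA transfer analysis
#'
#' @return Canonical names of 18:3n-3, 18:4n-3, 20:4n-3, 20:5n-3, 22:5n-3
#'   and 22:6n-3.
#' @export
omega3_acids <- function() {
  c("18:3n-3", "18:4n-3", "20:4n-3", "20:5n-3", "22:5n-3", "22:6n-3")
}

#' Sum of omega-3 polyunsaturated fatty acids
#'
#' Sums exactly the six n-3 acids of [omega3_acids()] in a fatty-acid
#' profile; acids absent from the profile contribute zero and acids of
#' other families never enter the sum.
#'
#' @param fa A data frame with columns `fa_name` and one or both of
#'   `pct_total` (% of total FA) and `conc_ug_L` (ug/L); typically the rows
#'   of one lake and compartment.
#' @return A one-row tibble with `omega3_pct` and `omega3_ug_L` (NA when
#'   the corresponding input column is absent).
#' @examples
#' fa <- data.frame(fa_name = c("20:5n-3", "22:6n-3", "18:2n-6"),
#'                  conc_ug_L = c(39.85, 85.5, 10))
#' omega3_sum(fa)$omega3_ug_L # 125.35
#' @export
omega3_sum <- function(fa) {
  if (!"fa_name" %in% names(fa)) {
    abort("omega3_sum(): need an fa_name column")
  }
  sel <- normalize_fa_name(fa$fa_name) %in% omega3_acids()
  sum_col <- function(col) {
    if (col %in% names(fa)) sum(fa[[col]][sel], na.rm = TRUE) else NA_real_
  }
  tibble::tibble(omega3_pct = sum_col("pct_total"),
                 omega3_ug_L = sum_col("conc_ug_L"))
}

#' Mass C:P ratio of an elemental composition
#'
#' @param c_pct,p_pct Carbon and phosphorus content, % of dry weight.
#' @param molar If TRUE, converts to a molar ratio (atomic masses 12.011
#'   and 30.974); default FALSE (mass ratio, the reporting convention the
#'   per-lake summaries use).
#' @return c_pct / p_pct (scaled by atomic masses when molar).
#' @examples
#' cp_ratio(47.7, 0.9) # 53.0
#' @export
cp_ratio <- function(c_pct, p_pct, molar = FALSE) {
  if (any(p_pct <= 0)) abort("cp_ratio(): p_pct must be > 0")
  r <- c_pct / p_pct
  if (molar) r * 30.974 / 12.011 else r
}

#' Mass C:N ratio of an elemental composition
#'
#' @param c_pct,n_pct Carbon and nitrogen content, % of dry weight.
#' @param molar If TRUE, molar ratio (atomic masses 12.011, 14.007).
#' @return c_pct / n_pct.
#' @export
cn_ratio <- function(c_pct, n_pct, molar = FALSE) {
  if (any(n_pct <= 0)) abort("cn_ratio(): n_pct must be > 0")
  r <- c_pct / n_pct
  if (molar) r * 14.007 / 12.011 else r
}

#' Fatty-acid trophic marker groups
#'
#' The source-group marker sets used to characterise seston fatty-acid
#' profiles: bacterial (branched and odd-chain acids plus 18:1n-7),
#' detrital (saturated even-chain), terrestrial (18:2n-6, 20:4n-6), diatom
#' (16:1n-7, 16:2n-4, 20:5n-3), green algae / cyanobacteria (16:2n-6,
#' 16:3n-3, 16:4n-3, 18:3n-3), dinophyte (22:6n-3) and
#' cryptophyte/flagellate (18:4n-3). Sum markers (s14:1, s17:1, s22:0+24:0)
#' are single profile keys at the reporting granularity of FAME tables.
#'
#' @return Named list of character vectors of canonical FA names.
#' @export
fa_marker_groups <- function() {
  list(
    bacteria = c("i14:0", "s14:1", "i15:0", "a15:0", "i15:1", "15:0",
                 "i16:0", "i17:0", "a17:0", "17:0", "s17:1", "18:1n-7"),
    detritus = c("16:0", "18:0", "20:0", "s22:0+24:0"),
    terrestrial = c("18:2n-6", "20:4n-6"),
    diatom = c("16:1n-7", "16:2n-4", "20:5n-3"),
    green_cyano = c("16:2n-6", "16:3n-3", "16:4n-3", "18:3n-3"),
    dinophyte = c("22:6n-3"),
    cryptophyte = c("18:4n-3")
  )
}

#' Aggregate a fatty-acid profile into marker groups
#'
#' Sums the % of total FA over each marker group; acids belonging to no
#' group are reported under `unassigned`.
#'
#' @param fa Data frame with `fa_name` and `pct_total` columns (one lake
#'   and compartment).
#' @param markers Marker sets, see [fa_marker_groups()].
#' @return Tibble with columns `marker_group` and `pct_total`.
#' @export
marker_aggregate <- function(fa, markers = fa_marker_groups()) {
  if (!all(c("fa_name", "pct_total") %in% names(fa))) {
    abort("marker_aggregate(): need fa_name and pct_total columns")
  }
  nm <- normalize_fa_name(fa$fa_name)
  assigned <- rep(FALSE, length(nm))
  rows <- purrr::imap(markers, function(acids, grp) {
    sel <- nm %in% normalize_fa_name(acids)
    assigned[sel] <<- TRUE
    tibble::tibble(marker_group = grp,
                   pct_total = sum(fa$pct_total[sel], na.rm = TRUE))
  })
  dplyr::bind_rows(rows) |>
    dplyr::bind_rows(tibble::tibble(
      marker_group = "unassigned",
      pct_total = sum(fa$pct_total[!assigned], na.rm = TRUE)
    ))
}

#' Per-lake composition summary table
#'
#' Convenience wrapper over a whole survey: stoichiometric ratios per lake
#' and compartment plus the omega-3 sums from the fatty-acid table.
#'
#' @param composition Table with `lake_id`, `compartment`, `c_pct`,
#'   `n_pct`, `p_pct` (and optionally `c_ug_L`).
#' @param fatty_acids Table with `lake_id`, `compartment`, `fa_name`,
#'   `pct_total`, `conc_ug_L`.
#' @return Tibble keyed by (lake_id, compartment) with `cp`, `cn`,
#'   `omega3_pct`, `omega3_ug_L`.
#' @export
composition_summary <- function(composition, fatty_acids) {
  ratios <- composition |>
    dplyr::mutate(cp = cp_ratio(.data$c_pct, .data$p_pct),
                  cn = cn_ratio(.data$c_pct, .data$n_pct)) |>
    dplyr::select(dplyr::any_of(c("lake_id", "compartment", "c_pct",
                                  "n_pct", "p_pct", "c_ug_L", "cp", "cn")))
  om <- fatty_acids |>
    dplyr::group_by(.data$lake_id, .data$compartment) |>
    dplyr::group_modify(~ omega3_sum(.x)) |>
    dplyr::ungroup()
  dplyr::left_join(ratios, om, by = c("lake_id", "compartment"))
}
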