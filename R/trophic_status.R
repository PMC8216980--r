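#' Carlson trophic state index components
#'
#' Computes the three Carlson (1977) trophic state index components from
#' Secchi disk visibility, chlorophyll a and total phosphorus:
#' \deqn{TSI(SD) = 60 - 14.41 \ln(SD)}
#' \deqn{TSI(Chl) = 9.81 \ln(Chl) + 30.6}
#' \deqn{TSI(TP) = 14.42 \ln(TP) + 4.15}
#' with SD in metres and chlorophyll a / TP in \eqn{\mu g/L}.
#'
#' @param data A data frame with one row per lake containing the columns
#'   named by `sdv`, `chl` and `tp`.
#' @param sdv,chl,tp Column names (strings) for Secchi depth (m),
#'   chlorophyll a (ug/L) and total phosphorus (ug/L).
#' @return The input as a tibble with columns `tsi_sd`, `tsi_chl`, `tsi_tp`
#'   appended.
#' @examples
#' tsi_components(data.frame(sdv_m = 1, chl_ug_L = 1, tp_ug_L = 1))
#' @export
tsi_components <- function(data, sdv = "sdv_m", chl = "chl_ug_L",
                           tp = "tp_ug_L") {
  need <- c(sdv, chl, tp)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("tsi_components(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  vals <- lapply(need, function(col) data[[col]])
  names(vals) <- c("sdv", "chl", "tp")
  bad <- vapply(vals, function(x) any(!is.na(x) & x <= 0), logical(1))
  if (any(bad)) {
    abort(paste0("tsi_components(): non-positive values in: ",
                 paste(need[bad], collapse = ", ")))
  }
  dplyr::as_tibble(data) |>
    dplyr::mutate(
      tsi_sd  = 60 - 14.41 * log(vals$sdv),
      tsi_chl = 9.81 * log(vals$chl) + 30.6,
      tsi_tp  = 14.42 * log(vals$tp) + 4.15
    )
}

#' Mean Carlson trophic state index
#'
#' The arithmetic mean of the three component indices (Secchi, chlorophyll,
#' total phosphorus), which is the single TSI value used to rank lakes.
#'
#' @inheritParams tsi_components
#' @return The input tibble with `tsi_sd`, `tsi_chl`, `tsi_tp` and their
#'   mean `tsi_mean` appended.
#' @export
carlson_tsi <- function(data, sdv = "sdv_m", chl = "chl_ug_L",
                        tp = "tp_ug_L") {
  tsi_components(data, sdv = sdv, chl = chl, tp = tp) |>
    dplyr::mutate(tsi_mean = (.data$tsi_sd + .data$tsi_chl + .data$tsi_tp) / 3)
}

#' Default hydrochemical dystrophy index coefficients
#'
#' The dystrophy index used here is a linear score in surface pH,
#' log10(electric conductivity) and the DIC/DOC ratio,
#' \deqn{HDI = c_0 - c_{pH}\,pH - c_{EC}\log_{10}(EC) - c_{R}\,(DIC/DOC),}
#' so that acidic, ion-poor, DOC-rich (humic) water scores high. The
#' published index this emulates is defined elsewhere and its coefficients
#' are not reproduced here; these defaults are calibrated so that typical
#' humic-lake chemistry (pH near 5, conductivity a few tens of uS/cm,
#' DIC/DOC well below 1) scores in the 60-80 band observed for strongly
#' dystrophic lakes, while clear-water lakes score far below the decision
#' threshold of 50. Override them for any real application.
#'
#' @return A named list with elements `intercept`, `ph`, `log10_ec`,
#'   `dic_doc` (the three slopes are subtracted).
#' @export
hdi_coefficients <- function() {
  list(intercept = 125, ph = 8, log10_ec = 10, dic_doc = 8)
}

#' Hydrochemical dystrophy index
#'
#' Scores each lake for dystrophy (humic character) from surface pH,
#' electric conductivity and the DIC/DOC ratio. The score is monotonically
#' decreasing in all three inputs under the default coefficients: dystrophic
#' lakes are acidic, ion-poor and DOC-rich.
#'
#' @param data Data frame with the chemistry columns.
#' @param coeffs Coefficient list as returned by [hdi_coefficients()].
#' @param ph,ec,dic,doc Column names for pH, conductivity (uS/cm), dissolved
#'   inorganic and organic carbon (mg/L).
#' @return Input tibble with an `hdi` column appended.
#' @export
hdi_score <- function(data, coeffs = hdi_coefficients(), ph = "ph",
                      ec = "ec_uS_cm", dic = "dic_mg_L", doc = "doc_mg_L") {
  need <- c(ph, ec, dic, doc)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("hdi_score(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.na(data[[doc]]) & data[[doc]] <= 0)) {
    abort("hdi_score(): DOC must be > 0 (DIC/DOC undefined otherwise)")
  }
  if (any(!is.na(data[[ec]]) & data[[ec]] <= 0)) {
    abort("hdi_score(): conductivity must be > 0")
  }
  dplyr::as_tibble(data) |>
    dplyr::mutate(
      hdi = coeffs$intercept -
        coeffs$ph * .data[[ph]] -
        coeffs$log10_ec * log10(.data[[ec]]) -
        coeffs$dic_doc * (.data[[dic]] / .data[[doc]])
    )
}

#' Assign trophic classes from TSI and the dystrophy index
#'
#' A lake is dystrophic iff its dystrophy index reaches `hdi_threshold`
#' (boundary included); otherwise the mean TSI is cut at `tsi_cuts` into
#' oligotrophic (< t1), mesotrophic ([t1, t2)) and eutrophic (>= t2).
#' Ties on a boundary resolve toward the higher-trophy class.
#'
#' @param tsi_mean,hdi Numeric vectors.
#' @param tsi_cuts Two ordered TSI cutoffs, default `c(40, 50)` (the
#'   conventional Carlson class boundaries).
#' @param hdi_threshold Dystrophy decision threshold, default 50.
#' @return A character vector with levels oligotrophic, mesotrophic,
#'   eutrophic, dystrophic.
#' @export
classify_trophic <- function(tsi_mean, hdi, tsi_cuts = c(40, 50),
                             hdi_threshold = 50) {
  if (length(tsi_cuts) != 2 || diff(tsi_cuts) <= 0) {
    abort("classify_trophic(): tsi_cuts must be two increasing values")
  }
  dplyr::case_when(
    hdi >= hdi_threshold ~ "dystrophic",
    tsi_mean < tsi_cuts[1] ~ "oligotrophic",
    tsi_mean < tsi_cuts[2] ~ "mesotrophic",
    TRUE ~ "eutrophic"
  )
}

#' Trophic assessment of a lake table
#'
#' One-call wrapper: computes the three TSI components, their mean, the
#' dystrophy index and the assigned class for every lake.
#'
#' @param lakes Lake chemistry table (`lakes` element of a survey, or any
#'   data frame with the standard chemistry columns).
#' @param coeffs Dystrophy-index coefficients, see [hdi_coefficients()].
#' @param tsi_cuts,hdi_threshold Classification thresholds, see
#'   [classify_trophic()].
#' @return A tibble with `lake_id`, `tsi_sd`, `tsi_chl`, `tsi_tp`,
#'   `tsi_mean`, `hdi` and `trophic_class`.
#' @examples
#' lakes <- data.frame(lake_id = "L1", sdv_m = 5.6, chl_ug_L = 2,
#'                     tp_ug_L = 8, ph = 8.3, ec_uS_cm = 280,
#'                     dic_mg_L = 22, doc_mg_L = 6)
#' assess_trophic(lakes)
#' @export
assess_trophic <- function(lakes, coeffs = hdi_coefficients(),
                           tsi_cuts = c(40, 50), hdi_threshold = 50) {
  lakes |>
    carlson_tsi() |>
    hdi_score(coeffs = coeffs) |>
    dplyr::mutate(trophic_class = classify_trophic(
      .data$tsi_mean, .data$hdi,
      tsi_cuts = tsi_cuts, hdi_threshold = hdi_threshold
    )) |>
    dplyr::select(dplyr::any_of("lake_id"), "tsi_sd", "tsi_chl", "tsi_tp",
                  "tsi_mean", "hdi", "trophic_class")
}

#' Canonical trophic class labels
#' @return Character vector of the four class labels in increasing-trophy
#'   order with dystrophic last.
#' @export
trophic_classes <- function() {
  c("oligotrophic", "mesotrophic", "eutrophic", "dystrophic")
}
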