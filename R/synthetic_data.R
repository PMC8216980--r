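# Lognormal draws re-parameterized to arithmetic mean / sd: positive field
# quantities (chlorophyll, TP, abundances) are right-skewed, so the
# generator uses lognormals whose *arithmetic* moments match the configured
# values; sd = 0 degenerates to the mean exactly.
rlnorm_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  if (any(mean < 0)) abort("rlnorm_ms(): mean must be >= 0")
  if (any(sd < 0)) abort("rlnorm_ms(): sd must be >= 0")
  if (any(mean == 0 & sd > 0)) {
    abort("rlnorm_ms(): zero mean with positive sd")
  }
  pos <- mean > 0
  sigma2 <- ifelse(pos, log(1 + (sd / pmax(mean, 1e-300))^2), 0)
  meanlog <- ifelse(pos, log(pmax(mean, 1e-300)) - sigma2 / 2, -Inf)
  draws <- rlnorm(n, meanlog = meanlog, sdlog = sqrt(sigma2))
  # sd = 0 degenerates to the configured mean exactly (no rounding through
  # exp(log(mean))); the RNG draw count stays fixed either way
  ifelse(sd == 0, mean, draws)
}

# normal clamped to a plausible physical range
rnorm_clamp <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# Deterministic per-lake RNG substream: a polynomial hash of the lake id
# mixed with the master seed, all arithmetic kept below 2^31 so the result
# is a valid integer seed. Makes lake draws independent of insertion order.
lake_substream_seed <- function(master_seed, lake_id) {
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% m)
  s <- (s * 48271) %% m
  h <- 0
  for (ch in utf8ToInt(as.character(lake_id))) h <- (h * 31 + ch) %% m
  as.integer((h + s) %% m)
}

default_assemblages <- function() {
  asm <- function(...) {
    tibble::tribble(
      ~species, ~group, ~abund_mean, ~abund_sd, ~length_mean_mm,
      ~length_sd_mm, ...
    )
  }
  clear <- asm(
    "Daphnia cucullata",         "Cladocera", 12, 8, 0.9, 0.15,
    "Daphnia cristata",          "Cladocera", 6, 4, 1.0, 0.15,
    "Diaphanosoma brachyurum",   "Cladocera", 8, 6, 0.8, 0.12,
    "Eudiaptomus graciloides",   "Copepoda", 10, 6, 1.1, 0.15,
    "Thermocyclops oithonoides", "Copepoda", 14, 9, 0.7, 0.10,
    "Conochilus unicornis",      "Rotifera", 40, 30, 0.25, 0.05
  )
  eutrophic <- asm(
    "Daphnia cucullata",         "Cladocera", 20, 14, 0.8, 0.12,
    "Bosmina thersites",         "Cladocera", 25, 18, 0.45, 0.08,
    "Chydorus sphaericus",       "Cladocera", 18, 12, 0.35, 0.06,
    "Thermocyclops oithonoides", "Copepoda", 22, 14, 0.7, 0.10,
    "Mesocyclops leuckarti",     "Copepoda", 12, 8, 0.9, 0.12,
    "Keratella cochlearis",      "Rotifera", 120, 90, 0.15, 0.03,
    "Pompholyx sulcata",         "Rotifera", 60, 45, 0.12, 0.03
  )
  dystrophic <- asm(
    "Asplanchna priodonta",      "Rotifera", 30, 25, 0.9, 0.2,
    "Ceriodaphnia quadrangula",  "Cladocera", 15, 10, 0.5, 0.08,
    "Eudiaptomus gracilis",      "Copepoda", 10, 7, 1.1, 0.15,
    "Bosmina longispina",        "Cladocera", 8, 6, 0.5, 0.08,
    "Mesocyclops leuckarti",     "Copepoda", 8, 6, 0.9, 0.12,
    "Diaphanosoma brachyurum",   "Cladocera", 6, 4, 0.8, 0.12
  )
  list(oligotrophic = clear, mesotrophic = clear, eutrophic = eutrophic,
       dystrophic = dystrophic)
}

default_fa_templates <- function() {
  # seston template dominated by detrital / bacterial / diatom markers
  # ("group 1" lakes); the green/cyanobacteria variant loads on 16:2n-6,
  # 16:3n-3, 16:4n-3, 18:3n-3 ("group 2"); zooplankton template is
  # LC-PUFA-enriched (selective feeding / retention).
  group1 <- c(
    "16:0" = 0.20, "18:0" = 0.05, "20:0" = 0.01, "s22:0+24:0" = 0.02,
    "i14:0" = 0.01, "s14:1" = 0.01, "i15:0" = 0.015, "a15:0" = 0.015,
    "i15:1" = 0.005, "15:0" = 0.01, "i16:0" = 0.01, "i17:0" = 0.005,
    "a17:0" = 0.005, "17:0" = 0.005, "s17:1" = 0.005, "18:1n-7" = 0.04,
    "18:2n-6" = 0.05, "20:4n-6" = 0.02,
    "16:1n-7" = 0.09, "16:2n-4" = 0.02, "20:5n-3" = 0.06,
    "16:2n-6" = 0.01, "16:3n-3" = 0.01, "16:4n-3" = 0.005,
    "18:3n-3" = 0.05,
    "22:6n-3" = 0.03, "18:4n-3" = 0.04, "20:4n-3" = 0.01,
    "22:5n-3" = 0.005, "18:1n-9" = 0.135, "14:0" = 0.05
  )
  group2 <- c(
    "16:0" = 0.16, "18:0" = 0.04, "20:0" = 0.005, "s22:0+24:0" = 0.01,
    "i14:0" = 0.005, "s14:1" = 0.005, "i15:0" = 0.005, "a15:0" = 0.005,
    "i15:1" = 0.0025, "15:0" = 0.005, "i16:0" = 0.005, "i17:0" = 0.0025,
    "a17:0" = 0.0025, "17:0" = 0.0025, "s17:1" = 0.0025, "18:1n-7" = 0.02,
    "18:2n-6" = 0.04, "20:4n-6" = 0.01,
    "16:1n-7" = 0.03, "16:2n-4" = 0.005, "20:5n-3" = 0.03,
    "16:2n-6" = 0.08, "16:3n-3" = 0.09, "16:4n-3" = 0.05,
    "18:3n-3" = 0.13,
    "22:6n-3" = 0.015, "18:4n-3" = 0.03, "20:4n-3" = 0.01,
    "22:5n-3" = 0.005, "18:1n-9" = 0.10, "14:0" = 0.04
  )
  zoo <- c(
    "16:0" = 0.18, "18:0" = 0.05, "14:0" = 0.03,
    "18:1n-7" = 0.05, "18:1n-9" = 0.10,
    "18:2n-6" = 0.04, "20:4n-6" = 0.03,
    "16:1n-7" = 0.05,
    "18:3n-3" = 0.06, "18:4n-3" = 0.05, "20:4n-3" = 0.01,
    "20:5n-3" = 0.16, "22:5n-3" = 0.01, "22:6n-3" = 0.12,
    "i15:0" = 0.01, "a15:0" = 0.01, "15:0" = 0.01, "17:0" = 0.01,
    "16:2n-6" = 0.01, "16:3n-3" = 0.01
  )
  norm <- function(x) x / sum(x)
  list(group1 = norm(group1), group2 = norm(group2), zoo = norm(zoo))
}

#' Synthetic lake-survey generator configuration
#'
#' Seeded, class-stratified distributional parameters for a synthetic
#' summer snapshot survey of stratified lakes in four trophic classes.
#' Class chlorophyll means/sds default to the whole-profile class averages
#' of the emulated survey (oligotrophic 4.79 +/- 7.95, mesotrophic
#' 5.97 +/- 5.92, eutrophic 14.62 +/- 17.56, dystrophic 47.65 +/- 35.76
#' ug/L); [table1_chlorophyll_preset()] gives the alternative surface-table
#' values. Positive quantities are drawn from lognormals matched to these
#' arithmetic moments. The `tte_structure` element sets per-class target
#' carbon transfer efficiencies; crustacean abundances are co-scaled
#' against each lake's modelled primary production so the pipeline recovers
#' these class means (parameter recovery).
#'
#' @param seed Master seed; per-lake substreams are derived by stable
#'   hashing of (seed, lake_id).
#' @param n_lakes_per_class Named integer vector over exactly the four
#'   classes (default 5/7/8/10, the emulated survey's design).
#' @param chl_mean_sd,sdv_mean_sd,tp_mean_sd Named lists class ->
#'   c(mean, sd) for chlorophyll a (ug/L), Secchi depth (m), total
#'   phosphorus (ug/L).
#' @param chemistry Named list class -> list(ph, ec, dic, doc), each a
#'   c(mean, sd): surface pH, conductivity (uS/cm), DIC and DOC (mg/L).
#' @param depth_layers Named list class -> data frame (layer, top_m,
#'   bottom_m), ordered, non-overlapping. Dystrophic lakes are shallow
#'   two-layer systems by default.
#' @param chl_vertical_mode Named character vector class ->
#'   "epilimnion-max", "metalimnion-max" or "uniform".
#' @param zoo_assemblage Named list class -> assemblage table (species,
#'   group, abund_mean, abund_sd, length_mean_mm, length_sd_mm).
#' @param seston_cp_mean_sd,seston_cn_mean_sd Named lists class ->
#'   c(mean, sd) of seston mass C:P and C:N.
#' @param zoo_composition List with `c_pct`, `cp`, `cn` c(mean, sd) for
#'   zooplankton (class-independent; consumer stoichiometry is
#'   homeostatic).
#' @param fa_profile_template Named list of FA proportion vectors (must
#'   each sum to 1): `group1` (detritus/bacteria/diatom-marker seston),
#'   `group2` (green-algae/cyanobacteria-marker seston), `zoo`.
#' @param green_seston_prob Named numeric class -> probability a lake
#'   draws the group2 seston template (dystrophic default 0.3, echoing the
#'   few humic lakes with green-algae marker enrichment).
#' @param tte_structure Named list class -> c(mean, sd) of target carbon
#'   TTE (%), defaults 14.31/8.0/4.28/2.89 with sds 6.5/4.0/4.49/3.45.
#' @param omega3_enrichment c(mean, sd) of the lognormal ratio of
#'   zooplankton to seston omega-3-per-carbon (default mean 3.2: PUFA
#'   transfer a few times more efficient than bulk carbon).
#' @param artefact_rate Probability that a lake's seston fatty-acid
#'   concentrations are under-measured 12-fold (trace-level measurement
#'   failure), producing impossible omega-3 efficiencies > 100%.
#' @param light List of light/production parameters: `par_surface`
#'   (umol m^-2 s^-1), `phi_mean`, `phi_sd`, plus the production-model
#'   parameters `p_max_per_chl`, `par_sat`, `daylength_hours` used for the
#'   TTE co-scaling.
#' @param c_to_chl Seston carbon to chlorophyll mass ratio (default 50).
#' @param ww_to_dw Wet-to-dry fraction used when co-scaling (default 0.10).
#' @return Object of class `lake_generator_config` (a validated list).
#' @export
generator_config <- function(
    seed = 1L,
    n_lakes_per_class = c(oligotrophic = 5, mesotrophic = 7,
                          eutrophic = 8, dystrophic = 10),
    chl_mean_sd = list(oligotrophic = c(4.79, 7.95),
                       mesotrophic = c(5.97, 5.92),
                       eutrophic = c(14.62, 17.56),
                       dystrophic = c(47.65, 35.76)),
    sdv_mean_sd = list(oligotrophic = c(5.6, 1.5),
                       mesotrophic = c(2.5, 1.1),
                       eutrophic = c(1.3, 0.6),
                       dystrophic = c(1.3, 0.5)),
    tp_mean_sd = list(oligotrophic = c(8, 3), mesotrophic = c(18, 6),
                      eutrophic = c(60, 30), dystrophic = c(35, 15)),
    chemistry = list(
      oligotrophic = list(ph = c(8.3, 0.3), ec = c(280, 60),
                          dic = c(22, 5), doc = c(6, 2)),
      mesotrophic = list(ph = c(8.2, 0.3), ec = c(300, 70),
                         dic = c(24, 6), doc = c(8, 2)),
      eutrophic = list(ph = c(8.4, 0.4), ec = c(320, 80),
                       dic = c(26, 6), doc = c(10, 3)),
      dystrophic = list(ph = c(5.0, 0.5), ec = c(28, 8),
                        dic = c(2.5, 1), doc = c(22, 8))
    ),
    depth_layers = NULL,
    chl_vertical_mode = c(oligotrophic = "metalimnion-max",
                          mesotrophic = "metalimnion-max",
                          eutrophic = "epilimnion-max",
                          dystrophic = "metalimnion-max"),
    zoo_assemblage = default_assemblages(),
    seston_cp_mean_sd = list(oligotrophic = c(150, 35),
                             mesotrophic = c(90, 20),
                             eutrophic = c(85, 20),
                             dystrophic = c(160, 45)),
    seston_cn_mean_sd = list(oligotrophic = c(8, 2.1),
                             mesotrophic = c(8, 2.1),
                             eutrophic = c(8, 2.1),
                             dystrophic = c(8, 2.1)),
    zoo_composition = list(c_pct = c(47.7, 1.7), cp = c(53.7, 13.0),
                           cn = c(4.9, 1.0)),
    fa_profile_template = default_fa_templates(),
    green_seston_prob = c(oligotrophic = 0.05, mesotrophic = 0.05,
                          eutrophic = 0.1, dystrophic = 0.3),
    tte_structure = list(oligotrophic = c(14.31, 6.50),
                         mesotrophic = c(8.0, 4.0),
                         eutrophic = c(4.28, 4.49),
                         dystrophic = c(2.89, 3.45)),
    omega3_enrichment = c(3.2, 1.5),
    artefact_rate = 0.1,
    light = list(par_surface = 1500, phi_mean = 0.65, phi_sd = 0.1,
                 p_max_per_chl = 4, par_sat = 180, daylength_hours = 16),
    c_to_chl = 50,
    ww_to_dw = 0.10) {
  if (is.null(depth_layers)) {
    deep <- tibble::tibble(layer = c("epilimnion", "metalimnion",
                                     "hypolimnion"),
                           top_m = c(0, 5, 10), bottom_m = c(5, 10, 18))
    shallow <- tibble::tibble(layer = c("epilimnion", "metalimnion"),
                              top_m = c(0, 2), bottom_m = c(2, 5))
    depth_layers <- list(oligotrophic = deep, mesotrophic = deep,
                         eutrophic = deep, dystrophic = shallow)
  }
  cfg <- structure(
    list(seed = seed, n_lakes_per_class = n_lakes_per_class,
         chl_mean_sd = chl_mean_sd, sdv_mean_sd = sdv_mean_sd,
         tp_mean_sd = tp_mean_sd, chemistry = chemistry,
         depth_layers = depth_layers,
         chl_vertical_mode = chl_vertical_mode,
         zoo_assemblage = zoo_assemblage,
         seston_cp_mean_sd = seston_cp_mean_sd,
         seston_cn_mean_sd = seston_cn_mean_sd,
         zoo_composition = zoo_composition,
         fa_profile_template = fa_profile_template,
         green_seston_prob = green_seston_prob,
         tte_structure = tte_structure,
         omega3_enrichment = omega3_enrichment,
         artefact_rate = artefact_rate, light = light,
         c_to_chl = c_to_chl, ww_to_dw = ww_to_dw),
    class = "lake_generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Surface-table chlorophyll preset
#'
#' Alternative class chlorophyll parameters corresponding to the emulated
#' survey's summary table of surface values (oligotrophic 9.2 +/- 13.2,
#' mesotrophic 7.5 +/- 2.3, eutrophic 29.2 +/- 21.9, dystrophic
#' 70.2 +/- 37.8 ug/L) rather than the whole-profile averages the default
#' configuration uses.
#'
#' @return Named list class -> c(mean, sd) suitable for the `chl_mean_sd`
#'   argument of [generator_config()].
#' @export
table1_chlorophyll_preset <- function() {
  list(oligotrophic = c(9.2, 13.2), mesotrophic = c(7.5, 2.3),
       eutrophic = c(29.2, 21.9), dystrophic = c(70.2, 37.8))
}

validate_generator_config <- function(cfg) {
  classes <- trophic_classes()
  check_keys <- function(x, field) {
    if (!setequal(names(x), classes)) {
      abort(paste0("generator_config(): '", field,
                   "' must have exactly the class keys ",
                   paste(classes, collapse = ", ")))
    }
  }
  check_ms <- function(x, field) {
    check_keys(x, field)
    for (cl in classes) {
      v <- x[[cl]]
      if (length(v) != 2 || v[1] <= 0 || v[2] < 0) {
        abort(paste0("generator_config(): '", field, "' for class ", cl,
                     " must be c(mean > 0, sd >= 0)"))
      }
    }
  }
  check_keys(cfg$n_lakes_per_class, "n_lakes_per_class")
  if (any(cfg$n_lakes_per_class < 0)) {
    abort("generator_config(): 'n_lakes_per_class' must be >= 0")
  }
  check_ms(cfg$chl_mean_sd, "chl_mean_sd")
  check_ms(cfg$sdv_mean_sd, "sdv_mean_sd")
  check_ms(cfg$tp_mean_sd, "tp_mean_sd")
  check_ms(cfg$seston_cp_mean_sd, "seston_cp_mean_sd")
  check_ms(cfg$seston_cn_mean_sd, "seston_cn_mean_sd")
  check_ms(cfg$tte_structure, "tte_structure")
  check_keys(cfg$depth_layers, "depth_layers")
  for (cl in classes) {
    dl <- cfg$depth_layers[[cl]]
    if (nrow(dl) < 1 || any(dl$bottom_m <= dl$top_m) ||
        (nrow(dl) > 1 && any(diff(dl$top_m) <= 0)) ||
        (nrow(dl) > 1 && any(dl$top_m[-1] < dl$bottom_m[-nrow(dl)] - 1e-9))) {
      abort(paste0("generator_config(): 'depth_layers' for class ", cl,
                   " must be ordered, non-overlapping intervals"))
    }
  }
  check_keys(cfg$chl_vertical_mode, "chl_vertical_mode")
  ok_modes <- c("epilimnion-max", "metalimnion-max", "uniform")
  if (!all(cfg$chl_vertical_mode %in% ok_modes)) {
    abort("generator_config(): 'chl_vertical_mode' values must be one of epilimnion-max, metalimnion-max, uniform")
  }
  check_keys(cfg$zoo_assemblage, "zoo_assemblage")
  for (cl in classes) {
    a <- cfg$zoo_assemblage[[cl]]
    if (nrow(a) > 0 && (any(a$abund_mean < 0) || any(a$abund_sd < 0))) {
      abort(paste0("generator_config(): 'zoo_assemblage' for class ", cl,
                   " has negative abundance parameters"))
    }
    if (nrow(a) > 0 &&
        !all(a$group %in% c("Cladocera", "Copepoda", "Rotifera"))) {
      abort(paste0("generator_config(): 'zoo_assemblage' for class ", cl,
                   " has an unknown species group"))
    }
  }
  for (nm in names(cfg$fa_profile_template)) {
    tot <- sum(cfg$fa_profile_template[[nm]])
    if (abs(tot - 1) > 1e-9) {
      abort(paste0("generator_config(): 'fa_profile_template' entry '", nm,
                   "' must sum to 1 (got ", format(tot), ")"))
    }
  }
  if (cfg$artefact_rate < 0 || cfg$artefact_rate > 1) {
    abort("generator_config(): 'artefact_rate' must be in [0, 1]")
  }
  invisible(cfg)
}

#' Generate one zooplankton sample
#'
#' Draws one layer's zooplankton community from an assemblage
#' specification: per species a lognormal abundance (ind/L, matched
#' arithmetic moments) and 10 measured body lengths (the standard
#' counting protocol measures 10 individuals per species), lognormal
#' around the species' length parameters.
#'
#' @param assemblage Assemblage table (columns `species`, `group`,
#'   `abund_mean`, `abund_sd`, `length_mean_mm`, `length_sd_mm`).
#' @param layer Layer name the sample belongs to.
#' @param seed Integer seed for this sample.
#' @param lake_id Lake identifier recorded in the output.
#' @param n_lengths Individuals measured per species (default 10).
#' @return Tibble in `zoo_counts` format: one row per measured individual
#'   with the species' abundance repeated.
#' @export
generate_zoo_sample <- function(assemblage, layer, seed, lake_id = "lake",
                                n_lengths = 10) {
  if (nrow(assemblage) == 0) {
    return(tibble::tibble(lake_id = character(), layer = character(),
                          species = character(), group = character(),
                          abundance_ind_L = numeric(),
                          length_mm = numeric()))
  }
  bad <- setdiff(assemblage$group, c("Cladocera", "Copepoda", "Rotifera"))
  if (length(bad) > 0) {
    abort(paste0("generate_zoo_sample(): unknown species group(s): ",
                 paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  ns <- nrow(assemblage)
  ab <- rlnorm_ms(ns, assemblage$abund_mean, assemblage$abund_sd)
  len <- rlnorm_ms(ns * n_lengths,
                   rep(assemblage$length_mean_mm, each = n_lengths),
                   rep(assemblage$length_sd_mm, each = n_lengths))
  tibble::tibble(
    lake_id = lake_id, layer = layer,
    species = rep(assemblage$species, each = n_lengths),
    group = rep(assemblage$group, each = n_lengths),
    abundance_ind_L = rep(ab, each = n_lengths),
    length_mm = len
  )
}

# layer chlorophyll multipliers before noise, by vertical mode
vertical_weights <- function(mode, n_layers) {
  w <- switch(mode,
    "epilimnion-max" = c(1, 0.4, 0.15),
    "metalimnion-max" = c(0.5, 1, 0.3),
    "uniform" = c(1, 1, 1)
  )
  w[seq_len(n_layers)]
}

# one lake's full observation set; cfg validated upstream
generate_one_lake <- function(cfg, cl, lake_id) {
  set.seed(lake_substream_seed(cfg$seed, lake_id))
  light <- cfg$light

  ## chemistry
  chem <- cfg$chemistry[[cl]]
  chl <- rlnorm_ms(1, cfg$chl_mean_sd[[cl]][1], cfg$chl_mean_sd[[cl]][2])
  sdv <- rlnorm_ms(1, cfg$sdv_mean_sd[[cl]][1], cfg$sdv_mean_sd[[cl]][2])
  tp <- rlnorm_ms(1, cfg$tp_mean_sd[[cl]][1], cfg$tp_mean_sd[[cl]][2])
  lakes <- tibble::tibble(
    lake_id = lake_id, true_class = cl,
    sdv_m = sdv, chl_ug_L = chl, tp_ug_L = tp,
    ph = rnorm_clamp(1, chem$ph[1], chem$ph[2], 3.5, 10),
    ec_uS_cm = rlnorm_ms(1, chem$ec[1], chem$ec[2]),
    dic_mg_L = rlnorm_ms(1, chem$dic[1], chem$dic[2]),
    doc_mg_L = rlnorm_ms(1, chem$doc[1], chem$doc[2])
  )

  ## layer profiles: chlorophyll placed by vertical mode, normalized so the
  ## unweighted profile mean equals the lake's drawn chlorophyll; PAR is the
  ## layer-mean of exponential attenuation under k = 1.7 / Secchi
  dl <- cfg$depth_layers[[cl]]
  nl <- nrow(dl)
  w <- vertical_weights(cfg$chl_vertical_mode[[cl]], nl)
  w <- w * rlnorm_ms(nl, 1, 0.2)
  w <- w / mean(w)
  k_ext <- 1.7 / sdv
  par_mean <- light$par_surface *
    (exp(-k_ext * dl$top_m) - exp(-k_ext * dl$bottom_m)) /
    (k_ext * (dl$bottom_m - dl$top_m))
  profiles <- tibble::tibble(
    lake_id = lake_id, layer = dl$layer, top_m = dl$top_m,
    bottom_m = dl$bottom_m, chl_ug_L = chl * w,
    phi_psii = rnorm_clamp(nl, light$phi_mean, light$phi_sd, 0.05, 0.95),
    par_umol_m2_s = par_mean
  )

  ## provisional zooplankton, then co-scale crustacean abundance so the
  ## pipeline's carbon TTE equals this lake's target draw
  asm <- cfg$zoo_assemblage[[cl]]
  zoo <- dplyr::bind_rows(purrr::map(seq_len(nl), function(i) {
    generate_zoo_sample(asm, dl$layer[i],
                        seed = lake_substream_seed(cfg$seed,
                                                   paste0(lake_id, "/",
                                                          dl$layer[i])),
                        lake_id = lake_id)
  }))
  set.seed(lake_substream_seed(cfg$seed, paste0(lake_id, "/targets")))
  tte_target <- min(rlnorm_ms(1, cfg$tte_structure[[cl]][1],
                              cfg$tte_structure[[cl]][2]), 95)

  # areal GPP and SP computed with the same primitives the pipeline uses,
  # but in plain vector form (the dplyr pipeline would dominate runtime
  # when thousands of lakes are simulated)
  consts <- conversion_constants(ww_to_dw = cfg$ww_to_dw)
  thick <- dl$bottom_m - dl$top_m
  lr <- light_response_registry()[["tanh_saturating"]]
  gpp_c_layer <- gpp_o2_to_carbon(
    lr(profiles$chl_ug_L, profiles$phi_psii, profiles$par_umol_m2_s,
       light$p_max_per_chl, light$par_sat, light$daylength_hours),
    consts
  )
  gpp_areal <- sum(gpp_c_layer * thick) / 1000

  allom <- default_allometry()
  sp_areal <- 0
  dw_layer <- setNames(numeric(nl), dl$layer)
  if (nrow(zoo) > 0) {
    ai <- allom$a[match(zoo$species, allom$species)]
    bi <- allom$b[match(zoo$species, allom$species)]
    mass <- individual_mass(zoo$length_mm, ai, bi)
    key <- paste(zoo$layer, zoo$species, sep = "\r")
    first <- !duplicated(key)
    mean_dw <- rowsum(mass, key)[, 1] /
      as.vector(table(key)[sort(unique(key))]) * cfg$ww_to_dw
    ab_key <- zoo$abundance_ind_L[first][match(names(mean_dw), key[first])]
    crust <- zoo$group[first][match(names(mean_dw), key[first])] !=
      "Rotifera"
    lay_key <- zoo$layer[first][match(names(mean_dw), key[first])]
    sp_dw <- numeric(length(mean_dw))
    sp_dw[crust] <- secondary_production(mean_dw[crust], ab_key[crust])
    sp_c_by_layer <- rowsum(dw_to_carbon(sp_dw, consts), lay_key)[, 1]
    sp_areal <- sum(sp_c_by_layer[dl$layer] * thick, na.rm = TRUE) / 1000
    dw_by_layer <- rowsum(mean_dw * ab_key, lay_key)[, 1]
    dw_layer[names(dw_by_layer)] <- dw_by_layer
  }
  scale_k <- 1
  if (sp_areal > 0 && gpp_areal > 0) {
    scale_k <- (tte_target / 100) * gpp_areal / sp_areal
    zoo$abundance_ind_L <- zoo$abundance_ind_L * scale_k
  }

  ## compositions: seston stoichiometry class-structured, zooplankton
  ## homeostatic
  s_c <- rnorm_clamp(1, 40, 3, 20, 60)
  s_cp <- rlnorm_ms(1, cfg$seston_cp_mean_sd[[cl]][1],
                    cfg$seston_cp_mean_sd[[cl]][2])
  s_cn <- rlnorm_ms(1, cfg$seston_cn_mean_sd[[cl]][1],
                    cfg$seston_cn_mean_sd[[cl]][2])
  z_c <- rnorm_clamp(1, cfg$zoo_composition$c_pct[1],
                     cfg$zoo_composition$c_pct[2], 30, 60)
  z_cp <- rlnorm_ms(1, cfg$zoo_composition$cp[1], cfg$zoo_composition$cp[2])
  z_cn <- rlnorm_ms(1, cfg$zoo_composition$cn[1], cfg$zoo_composition$cn[2])
  seston_c_ug_L <- chl * cfg$c_to_chl

  # biomass is linear in abundance, so the scaled dry mass is scale_k times
  # the provisional one
  zoo_dw_ug_L <- scale_k * sum(dw_layer * thick) / sum(thick)
  zoo_c_ug_L <- zoo_dw_ug_L * z_c / 100

  composition <- tibble::tibble(
    lake_id = lake_id,
    compartment = c("seston", "zooplankton"),
    c_pct = c(s_c, z_c),
    n_pct = c(s_c / s_cn, z_c / z_cn),
    p_pct = c(s_c / s_cp, z_c / z_cp),
    c_ug_L = c(seston_c_ug_L, zoo_c_ug_L)
  )

  ## fatty acids: Dirichlet-style noise around the class template
  tmpl <- cfg$fa_profile_template
  use_green <- runif(1) < cfg$green_seston_prob[[cl]]
  s_tmpl <- if (use_green) tmpl$group2 else tmpl$group1
  draw_profile <- function(template, conc_alpha = 150) {
    g <- rgamma(length(template), shape = conc_alpha * template)
    out <- if (sum(g) == 0) template else g / sum(g)
    setNames(out, names(template))
  }
  s_prop <- draw_profile(s_tmpl)
  z_prop <- draw_profile(tmpl$zoo)
  total_fa_seston <- 0.04 * seston_c_ug_L * rlnorm_ms(1, 1, 0.3)
  s_conc <- total_fa_seston * s_prop
  omega3_share_seston <- sum(
    s_prop[normalize_fa_name(names(s_prop)) %in% omega3_acids()]
  )
  omega3_seston_per_c <- total_fa_seston * omega3_share_seston /
    seston_c_ug_L
  enrich <- rlnorm_ms(1, cfg$omega3_enrichment[1], cfg$omega3_enrichment[2])
  omega3_zoo_ug_L <- enrich * omega3_seston_per_c * zoo_c_ug_L
  omega3_share_zoo <- sum(
    z_prop[normalize_fa_name(names(z_prop)) %in% omega3_acids()]
  )
  total_fa_zoo <- omega3_zoo_ug_L / omega3_share_zoo
  z_conc <- total_fa_zoo * z_prop
  artefact <- runif(1) < cfg$artefact_rate
  if (artefact) s_conc <- s_conc / 12 # seston FA under-measured

  fatty_acids <- dplyr::bind_rows(
    tibble::tibble(lake_id = lake_id, compartment = "seston",
                   fa_name = names(s_prop), pct_total = 100 * s_prop,
                   conc_ug_L = s_conc),
    tibble::tibble(lake_id = lake_id, compartment = "zooplankton",
                   fa_name = names(z_prop), pct_total = 100 * z_prop,
                   conc_ug_L = z_conc)
  )

  list(lakes = lakes, profiles = profiles, zoo_counts = zoo,
       composition = composition, fatty_acids = fatty_acids)
}

#' Generate a synthetic lake survey set
#'
#' Draws the configured number of lakes per trophic class, each with
#' chemistry, layered chlorophyll/PSII/PAR profiles, zooplankton counts
#' and lengths, elemental compositions and fatty-acid profiles. The same
#' configuration (including seed) always reproduces the identical survey;
#' each lake has its own RNG substream so results do not depend on
#' generation order.
#'
#' @param config A [generator_config()].
#' @return Object of class `lake_survey_set`: named list of tibbles
#'   `lakes`, `profiles`, `zoo_counts`, `composition`, `fatty_acids`.
#' @examples
#' cfg <- generator_config(n_lakes_per_class = c(
#'   oligotrophic = 1, mesotrophic = 1, eutrophic = 1, dystrophic = 1))
#' sv <- generate_survey(cfg)
#' sv$lakes
#' @export
generate_survey <- function(config = generator_config()) {
  validate_generator_config(config)
  classes <- trophic_classes()
  abbrev <- c(oligotrophic = "oligo", mesotrophic = "meso",
              eutrophic = "eu", dystrophic = "dys")
  pieces <- list()
  for (cl in classes) {
    n <- config$n_lakes_per_class[[cl]]
    if (n == 0) next
    for (i in seq_len(n)) {
      lake_id <- sprintf("%s_%03d", abbrev[[cl]], i)
      pieces[[lake_id]] <- generate_one_lake(config, cl, lake_id)
    }
  }
  bind_part <- function(part) {
    dplyr::bind_rows(purrr::map(pieces, part))
  }
  structure(
    list(lakes = bind_part("lakes"), profiles = bind_part("profiles"),
         zoo_counts = bind_part("zoo_counts"),
         composition = bind_part("composition"),
         fatty_acids = bind_part("fatty_acids")),
    class = "lake_survey_set", config = config
  )
}

#' @export
print.lake_survey_set <- function(x, ...) {
  cat("Synthetic lake survey:", nrow(x$lakes), "lakes\n")
  print(table(x$lakes$true_class))
  invisible(x)
}
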