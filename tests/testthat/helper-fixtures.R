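# small survey configurations and toy tables shared across tests

tiny_config <- function(seed = 101, n = c(oligotrophic = 1, mesotrophic = 1,
                                          eutrophic = 1, dystrophic = 1)) {
  generator_config(seed = seed, n_lakes_per_class = n)
}

# a single-class config, handy for class-specific structure checks
class_config <- function(class, n, seed = 101) {
  counts <- c(oligotrophic = 0, mesotrophic = 0, eutrophic = 0,
              dystrophic = 0)
  counts[class] <- n
  generator_config(seed = seed, n_lakes_per_class = counts)
}

# degenerate config: every distribution collapsed to its mean
degenerate_config <- function(seed = 1) {
  cfg <- generator_config(seed = seed, n_lakes_per_class = c(
    oligotrophic = 1, mesotrophic = 1, eutrophic = 1, dystrophic = 1))
  zero_sd <- function(x) lapply(x, function(v) c(v[1], 0))
  cfg$chl_mean_sd <- zero_sd(cfg$chl_mean_sd)
  cfg$sdv_mean_sd <- zero_sd(cfg$sdv_mean_sd)
  cfg$tp_mean_sd <- zero_sd(cfg$tp_mean_sd)
  cfg$chemistry <- lapply(cfg$chemistry, function(ch) {
    lapply(ch, function(v) c(v[1], 0))
  })
  cfg
}

toy_allometry <- function(species = "sp", group = "Cladocera", a = 10,
                          b = 0) {
  tibble::tibble(species = species, group = group, a = a, b = b,
                 output_basis = "wet_ug", source = "toy")
}

toy_zoo <- function(lake_id = "L1", layer = "epilimnion", species = "sp",
                    group = "Cladocera", abundance = 100, lengths = 1) {
  tibble::tibble(lake_id = lake_id, layer = layer, species = species,
                 group = group, abundance_ind_L = abundance,
                 length_mm = lengths)
}

dystrophic_chemistry <- function() {
  data.frame(lake_id = "humic", sdv_m = 1.3, chl_ug_L = 47.65,
             tp_ug_L = 35, ph = 5.0, ec_uS_cm = 28, dic_mg_L = 2.5,
             doc_mg_L = 22)
}

clearwater_chemistry <- function() {
  data.frame(lake_id = "clear", sdv_m = 5.6, chl_ug_L = 4.79, tp_ug_L = 8,
             ph = 8.3, ec_uS_cm = 280, dic_mg_L = 22, doc_mg_L = 6)
}
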