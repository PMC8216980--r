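#' Survey CSV schemas
#'
#' The fixed column sets of the five survey tables. Units are embedded in
#' the column names to prevent unit drift; missing values are empty cells
#' and propagate as NA, never silently zero.
#'
#' @return Named list: table name -> required column names.
#' @export
survey_schemas <- function() {
  list(
    lakes = c("lake_id", "sdv_m", "chl_ug_L", "tp_ug_L", "ph", "ec_uS_cm",
              "dic_mg_L", "doc_mg_L"),
    profiles = c("lake_id", "layer", "top_m", "bottom_m", "chl_ug_L",
                 "phi_psii", "par_umol_m2_s"),
    zoo_counts = c("lake_id", "layer", "species", "group",
                   "abundance_ind_L", "length_mm"),
    composition = c("lake_id", "compartment", "c_pct", "n_pct", "p_pct"),
    fatty_acids = c("lake_id", "compartment", "fa_name", "pct_total",
                    "conc_ug_L")
  )
}

#' Write a survey to CSV files
#'
#' @param survey A `lake_survey_set` (from [generate_survey()] or
#'   [read_survey()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(survey_schemas())) {
    readr::write_csv(survey[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

# row-level validation rules; each returns indices of offending rows
survey_row_checks <- function() {
  list(
    lakes = function(df) which(
      df$sdv_m <= 0 | df$chl_ug_L <= 0 | df$tp_ug_L <= 0 |
        df$ph <= 0 | df$ph >= 14 | df$doc_mg_L <= 0
    ),
    profiles = function(df) which(
      df$bottom_m <= df$top_m | df$chl_ug_L < 0 |
        df$phi_psii < 0 | df$phi_psii > 1 | df$par_umol_m2_s < 0
    ),
    zoo_counts = function(df) which(
      df$abundance_ind_L < 0 | (!is.na(df$length_mm) & df$length_mm <= 0)
    ),
    composition = function(df) which(
      df$c_pct <= 0 | df$c_pct >= 100 | df$n_pct <= 0 | df$p_pct <= 0 |
        !(df$compartment %in% c("seston", "zooplankton"))
    ),
    fatty_acids = function(df) which(
      df$pct_total < 0 | !(df$compartment %in% c("seston", "zooplankton"))
    )
  )
}

#' Read a survey from CSV files
#'
#' Loads and validates the five survey tables written by [write_survey()]
#' (see [survey_schemas()]). A missing required column is always an error.
#' Row-level violations (negative abundances, inverted layer bounds, ...)
#' abort with the offending file and row numbers unless `permissive =
#' TRUE`, in which case the offending rows are dropped with a warning and
#' everything valid still loads.
#'
#' @param dir Directory containing the CSVs.
#' @param permissive Drop bad rows instead of failing (default FALSE).
#' @return A `lake_survey_set`.
#' @export
read_survey <- function(dir, permissive = FALSE) {
  schemas <- survey_schemas()
  checks <- survey_row_checks()
  out <- list()
  for (nm in names(schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      abort(paste0("read_survey(): missing file ", path))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(schemas[[nm]], names(df))
    if (length(miss) > 0) {
      abort(paste0("read_survey(): ", nm, ".csv lacks required column(s): ",
                   paste(miss, collapse = ", ")))
    }
    bad <- checks[[nm]](df)
    bad <- bad[!is.na(bad)]
    if (length(bad) > 0) {
      msg <- paste0(nm, ".csv: invalid value(s) in row(s) ",
                    paste(head(bad, 10), collapse = ", "),
                    if (length(bad) > 10) ", ..." else "")
      if (permissive) {
        warn(paste0("read_survey() dropped rows - ", msg))
        df <- df[-bad, , drop = FALSE]
      } else {
        abort(paste0("read_survey(): ", msg,
                     " (use permissive = TRUE to drop them)"))
      }
    }
    out[[nm]] <- dplyr::as_tibble(df)
  }
  # referential integrity: zoo samples must point at existing layers
  keys <- paste(out$profiles$lake_id, out$profiles$layer)
  orphan <- !(paste(out$zoo_counts$lake_id, out$zoo_counts$layer) %in% keys)
  if (any(orphan)) {
    msg <- paste0("zoo_counts.csv references unknown lake/layer in row(s) ",
                  paste(head(which(orphan), 10), collapse = ", "))
    if (permissive) {
      warn(paste0("read_survey() dropped rows - ", msg))
      out$zoo_counts <- out$zoo_counts[!orphan, , drop = FALSE]
    } else {
      abort(paste0("read_survey(): ", msg))
    }
  }
  structure(out, class = "lake_survey_set")
}

#' Pipeline configuration
#'
#' Assembles and validates all knobs of an end-to-end run: either a
#' generator configuration (simulation mode) or an input directory of
#' survey CSVs, plus constants, thresholds and model selections.
#'
#' @param generator A [generator_config()] for simulation mode, or NULL.
#' @param input_dir Directory of survey CSVs (ignored in generator mode).
#' @param output_dir Where result CSVs are written; NULL for none.
#' @param constants [conversion_constants()].
#' @param tsi_cuts,hdi_threshold Classification thresholds.
#' @param alpha Significance level for the statistics stage, in (0, 1).
#' @param p_max_per_chl,par_sat,daylength_hours,light_model Production
#'   model selection (must match the generator's co-scaling parameters in
#'   simulation mode; the defaults do).
#' @param linkage Clustering linkage for the community dendrograms.
#' @param constrained_ordination Use trophic class as the CCA constraint
#'   (TRUE) or run unconstrained CA (FALSE, default).
#' @param allometry Length-weight table, see [default_allometry()].
#' @param class_col Class labels used for grouping summaries:
#'   "trophic_class" (assessed, default) or "true_class" (generator truth,
#'   simulation mode only).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_dir = NULL,
                            output_dir = NULL,
                            constants = conversion_constants(),
                            tsi_cuts = c(40, 50), hdi_threshold = 50,
                            alpha = 0.05, p_max_per_chl = 4,
                            par_sat = 180, daylength_hours = 16,
                            light_model = "tanh_saturating",
                            linkage = "average",
                            constrained_ordination = FALSE,
                            allometry = NULL,
                            class_col = "trophic_class") {
  if (is.null(generator) && is.null(input_dir)) {
    abort("pipeline_config(): need a generator config or an input_dir")
  }
  if (!is.null(generator)) validate_generator_config(generator)
  if (is.null(generator) && !dir.exists(input_dir)) {
    abort(paste0("pipeline_config(): input_dir does not exist: ", input_dir))
  }
  if (length(tsi_cuts) != 2 || diff(tsi_cuts) <= 0) {
    abort("pipeline_config(): tsi_cuts must be two increasing values")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("pipeline_config(): alpha must be in (0, 1)")
  }
  if (!light_model %in% light_response_models()) {
    abort(paste0("pipeline_config(): unknown light model '", light_model,
                 "'"))
  }
  structure(
    list(generator = generator, input_dir = input_dir,
         output_dir = output_dir, constants = constants,
         tsi_cuts = tsi_cuts, hdi_threshold = hdi_threshold, alpha = alpha,
         p_max_per_chl = p_max_per_chl, par_sat = par_sat,
         daylength_hours = daylength_hours, light_model = light_model,
         linkage = linkage,
         constrained_ordination = constrained_ordination,
         allometry = allometry, class_col = class_col),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file's top-level keys onto [pipeline_config()] arguments;
#' a `generator:` block with a `seed` and optional `n_lakes_per_class`
#' map enables simulation mode.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) {
    gargs <- list()
    if (!is.null(y$generator$seed)) gargs$seed <- y$generator$seed
    if (!is.null(y$generator$n_lakes_per_class)) {
      gargs$n_lakes_per_class <- unlist(y$generator$n_lakes_per_class)
    }
    gen <- do.call(generator_config, gargs)
  }
  args <- y[setdiff(names(y), "generator")]
  if (!is.null(args$tsi_cuts)) args$tsi_cuts <- unlist(args$tsi_cuts)
  do.call(pipeline_config, c(list(generator = gen), args))
}

# tiny FNV-1a hash for the run manifest (no binary artefacts, reproducible)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the whole transfer-efficiency pipeline
#'
#' Executes every stage in order: trophic assessment, biomass, production,
#' composition/TTE, class summaries and the statistics layer (per-substance
#' ANOVA + LSD letters). In generator mode the survey is simulated first.
#' When `output_dir` is set, writes `assessments.csv`, `biomass.csv`,
#' `production.csv`, `tte.csv`, `tte_summary.csv`, `stats/anova.csv`,
#' `stats/letters.csv` and a machine-readable `manifest.json` (config
#' hash, seed, package version). Deterministic given the generator seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with `survey`, `assessments`,
#'   `biomass`, `production` (list of layers/areal), `tte`, `tte_summary`
#'   and `stats` (per-substance list of `oneway_anova`/`fisher_lsd`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  res <- tryCatch({
    survey <- if (!is.null(config$generator)) {
      generate_survey(config$generator)
    } else {
      read_survey(config$input_dir)
    }

    stage <- "trophic_status"
    assessments <- assess_trophic(survey$lakes, tsi_cuts = config$tsi_cuts,
                                  hdi_threshold = config$hdi_threshold)
    if ("true_class" %in% names(survey$lakes)) {
      assessments <- dplyr::left_join(
        assessments,
        dplyr::select(survey$lakes, "lake_id", "true_class"),
        by = "lake_id"
      )
    }

    stage <- "biomass"
    allom <- config$allometry %||% default_allometry()
    biomass <- sample_biomass(survey$zoo_counts, allometry = allom,
                              ww_to_dw = config$constants$ww_to_dw)

    stage <- "production"
    production <- compute_production(
      survey$profiles, biomass, model = config$light_model,
      p_max_per_chl = config$p_max_per_chl, par_sat = config$par_sat,
      daylength_hours = config$daylength_hours,
      constants = config$constants
    )

    stage <- "tte"
    tte <- compute_tte(production$areal, survey$composition,
                       survey$fatty_acids, biomass = biomass)
    class_tbl <- if (config$class_col == "true_class") {
      dplyr::select(survey$lakes, "lake_id", "true_class")
    } else {
      assessments
    }
    tte_summary <- summarize_tte(tte, class_tbl,
                                 class_col = config$class_col)

    stage <- "stats"
    tte_cls <- dplyr::inner_join(
      tte, dplyr::select(class_tbl, "lake_id",
                         cls = dplyr::all_of(config$class_col)),
      by = "lake_id"
    )
    stats_out <- purrr::map(setNames(nm = unique(tte$substance)),
                            function(sub) {
      df <- tte_cls |>
        dplyr::filter(.data$substance == sub, !.data$artefact,
                      !is.na(.data$tte_pct))
      if (length(unique(df$cls)) < 2 || nrow(df) <= length(unique(df$cls))) {
        return(NULL)
      }
      fit <- one_way_anova(df, "tte_pct", "cls")
      list(anova = fit, lsd = fisher_lsd(fit, alpha = config$alpha))
    })

    bundle <- list(survey = survey, assessments = assessments,
                   biomass = biomass, production = production, tte = tte,
                   tte_summary = tte_summary, stats = stats_out)

    if (!is.null(config$output_dir)) {
      stage <- "output"
      dir.create(file.path(config$output_dir, "stats"), recursive = TRUE,
                 showWarnings = FALSE)
      w <- function(df, f) {
        readr::write_csv(df, file.path(config$output_dir, f),
                         progress = FALSE)
      }
      w(assessments, "assessments.csv")
      w(biomass, "biomass.csv")
      w(production$layers, "production.csv")
      w(dplyr::inner_join(tte, dplyr::select(class_tbl, "lake_id",
                          class = dplyr::all_of(config$class_col)),
                          by = "lake_id"), "tte.csv")
      w(tte_summary, "tte_summary.csv")
      anova_tbl <- purrr::imap(stats_out, function(s, sub) {
        if (is.null(s)) return(NULL)
        dplyr::mutate(glance(s$anova), substance = sub, .before = 1)
      }) |> dplyr::bind_rows()
      letters_tbl <- purrr::imap(stats_out, function(s, sub) {
        if (is.null(s)) return(NULL)
        dplyr::mutate(s$lsd$letters, substance = sub, .before = 1)
      }) |> dplyr::bind_rows()
      w(anova_tbl, file.path("stats", "anova.csv"))
      w(letters_tbl, file.path("stats", "letters.csv"))
      # the hash identifies the scientific configuration; where the
      # results land is not part of the run's identity
      hash_cfg <- unclass(config)
      hash_cfg$output_dir <- NULL
      manifest <- list(
        config_hash = fnv1a_hash(hash_cfg),
        seed = config$generator$seed %||% NA,
        package_version = as.character(utils::packageVersion("limnotte"))
      )
      jsonlite::write_json(manifest,
                           file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    bundle
  }, error = function(e) {
    abort(paste0("run_pipeline() failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(res)
}
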