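#' Box plot of transfer efficiencies by trophic class
#'
#' The standard presentation of the per-class comparison: boxes are the
#' first and third quartiles, the bar the median, a cross the mean,
#' whiskers min and max (artefacts excluded), and LSD compact letters
#' above each box.
#'
#' @param tte Output of [compute_tte()].
#' @param classes Class mapping as in [summarize_tte()].
#' @param substance Which substance to plot (default "C").
#' @param class_col Class column name in `classes`.
#' @param alpha LSD significance level for the letters.
#' @return A ggplot object.
#' @export
plot_tte_box <- function(tte, classes, substance = "C",
                         class_col = "trophic_class", alpha = 0.05) {
  sub <- substance
  df <- tte |>
    dplyr::filter(.data$substance == sub, !.data$artefact,
                  !is.na(.data$tte_pct)) |>
    dplyr::inner_join(
      dplyr::select(classes, "lake_id", cls = dplyr::all_of(class_col)),
      by = "lake_id"
    ) |>
    dplyr::mutate(cls = factor(.data$cls, levels = trophic_classes()))
  letters_df <- NULL
  if (length(unique(df$cls)) >= 2 && nrow(df) > length(unique(df$cls))) {
    fit <- one_way_anova(df, "tte_pct", "cls")
    lsd <- fisher_lsd(fit, alpha = alpha)
    tops <- df |>
      dplyr::group_by(group = as.character(.data$cls)) |>
      dplyr::summarise(top = max(.data$tte_pct), .groups = "drop")
    letters_df <- dplyr::inner_join(lsd$letters, tops, by = "group") |>
      dplyr::mutate(cls = factor(.data$group, levels = trophic_classes()))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cls, y = .data$tte_pct)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4,
                          size = 2.5) +
    ggplot2::labs(x = NULL, y = paste0("TTE of ", substance, " (%)")) +
    ggplot2::theme_minimal()
  if (!is.null(letters_df)) {
    p <- p + ggplot2::geom_text(
      data = letters_df,
      ggplot2::aes(x = .data$cls, y = .data$top, label = .data$letters),
      vjust = -0.8, fontface = "italic"
    )
  }
  p
}

#' Ordination biplot
#'
#' Sites and variables of a correspondence analysis in the first two
#' dimensions, axis labels annotated with the inertia fractions.
#'
#' @param object A `lake_ca` from [correspondence_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lake_ca
#' @export
autoplot.lake_ca <- function(object, ...) {
  if (length(object$eigenvalues) < 2) {
    abort("autoplot.lake_ca(): need at least two dimensions to plot")
  }
  df <- tidy(object)
  lab <- function(i) {
    sprintf("Dimension %d (%.1f%% of inertia)", i,
            100 * object$inertia_fractions[i])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$score_type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3,
                       show.legend = FALSE) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Vertical chlorophyll profiles of a survey
#'
#' One step-line per lake of layer chlorophyll against depth, faceted by
#' trophic class; visualises where each class places its chlorophyll
#' maximum (epilimnetic in eutrophic lakes, deeper in clear ones).
#'
#' @param survey A `lake_survey_set`.
#' @return A ggplot object.
#' @export
plot_chl_profiles <- function(survey) {
  df <- survey$profiles |>
    dplyr::left_join(
      dplyr::select(survey$lakes, "lake_id",
                    dplyr::any_of("true_class")),
      by = "lake_id"
    ) |>
    dplyr::mutate(mid_m = (.data$top_m + .data$bottom_m) / 2)
  aes_args <- ggplot2::aes(x = .data$chl_ug_L, y = .data$mid_m,
                           group = .data$lake_id)
  p <- ggplot2::ggplot(df, aes_args) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Chlorophyll a (ug/L)", y = "Depth (m)") +
    ggplot2::theme_minimal()
  if ("true_class" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~true_class, scales = "free_x")
  }
  p
}
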