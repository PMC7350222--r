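#' Plot cumulative vaccine efficacy by group
#'
#' Bar chart of the cumulative efficacy of every (formulation, breed, tick
#' species) group, faceted by breed.
#'
#' @param efficacy Output of [vaccine_efficacy()].
#' @return A ggplot object.
#' @export
plot_efficacy <- function(efficacy) {
  ggplot2::ggplot(efficacy,
                  ggplot2::aes(x = .data$tick_species,
                               y = .data$efficacy_pct,
                               fill = .data$antigen_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$breed)) +
    ggplot2::labs(x = NULL, y = "Vaccine efficacy E (%)",
                  fill = "Formulation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot antibody response time courses
#'
#' Mean OD450 per group over the bleed schedule, one panel per coated
#' antigen, coloured by formulation.
#'
#' @param serology Serology tibble (see [read_serology()]).
#' @return A ggplot object.
#' @export
plot_titer_timecourse <- function(serology) {
  means <- serology |>
    dplyr::group_by(.data$breed, .data$antigen_group, .data$coated_antigen,
                    .data$day) |>
    dplyr::summarise(od450 = mean(.data$od450), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$day, y = .data$od450,
                                      colour = .data$antigen_group)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$breed),
                        ggplot2::vars(.data$coated_antigen)) +
    ggplot2::labs(x = "Day", y = "OD450", colour = "Formulation") +
    ggplot2::theme_minimal()
}

#' Plot titer-outcome correlations
#'
#' Rho per stage parameter with significance highlighted, one panel per
#' (breed, tick species).
#'
#' @param correlations Output of [correlate_titers_stages()] (optionally with
#'   `breed` / `tick_species` columns from the pipeline).
#' @return A ggplot object.
#' @export
plot_titer_correlation <- function(correlations) {
  p <- ggplot2::ggplot(correlations,
                       ggplot2::aes(x = .data$parameter, y = .data$rho,
                                    fill = .data$significant_negative)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      name = "Significant negative") +
    ggplot2::labs(x = "Stage parameter", y = "Spearman's rho") +
    ggplot2::theme_minimal()
  if (all(c("breed", "tick_species") %in% names(correlations))) {
    p <- p + ggplot2::facet_grid(ggplot2::vars(.data$breed),
                                 ggplot2::vars(.data$tick_species))
  }
  p
}

#' Autoplot method for trial analyses
#'
#' @param object A `tickvax_analysis`.
#' @param type One of `"efficacy"` (default), `"timecourse"` (requires the
#'   serology to have been analysed), `"correlation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tickvax_analysis
#' @export
autoplot.tickvax_analysis <- function(object, type = c("efficacy",
                                                       "timecourse",
                                                       "correlation"), ...) {
  type <- match.arg(type)
  switch(type,
    efficacy = plot_efficacy(object$efficacy),
    timecourse = {
      if (is.null(object$timecourse)) {
        rlang::abort("analysis carries no antibody time-course results")
      }
      means <- object$timecourse
      ggplot2::ggplot(means, ggplot2::aes(x = .data$day,
                                          y = .data$statistic,
                                          colour = .data$antigen_group)) +
        ggplot2::geom_line() +
        ggplot2::facet_grid(ggplot2::vars(.data$breed),
                            ggplot2::vars(.data$coated_antigen)) +
        ggplot2::labs(x = "Day", y = "F statistic",
                      colour = "Formulation") +
        ggplot2::theme_minimal()
    },
    correlation = {
      if (is.null(object$correlations)) {
        rlang::abort("analysis carries no correlation results")
      }
      plot_titer_correlation(object$correlations)
    })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
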