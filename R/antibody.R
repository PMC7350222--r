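#' Per-timepoint antibody-titer comparison between vaccinated and control
#'
#' For every (breed, formulation, coated antigen, bleed day) cell, compares
#' the vaccinated group's OD450 readings against the matching control group
#' with a one-way ANOVA, coding significance at two levels (p < 0.05 and
#' p < 0.005).
#'
#' @param serology Tibble with columns `animal_id`, `breed`, `antigen_group`,
#'   `coated_antigen`, `day`, `od450`.
#' @param alpha Primary significance level; the stronger level is
#'   `alpha / 10`.
#' @param control_group Label of the control arm.
#' @return Tibble with one row per cell: group labels, `day`, `n_vaccinated`,
#'   `n_control`, `statistic` (F), `p_value`, `signif_label` (`""`, `"*"`,
#'   `"**"`).
#' @export
titer_timecourse_test <- function(serology, alpha = 0.05,
                                  control_group = "control") {
  serology <- tibble::as_tibble(serology)
  needed <- c("animal_id", "breed", "antigen_group", "coated_antigen",
              "day", "od450")
  missing <- setdiff(needed, names(serology))
  if (length(missing) > 0) {
    rlang::abort(paste0("serology table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  cells <- serology |>
    dplyr::filter(.data$antigen_group != control_group) |>
    dplyr::distinct(.data$breed, .data$antigen_group, .data$coated_antigen,
                    .data$day)
  purrr::pmap_dfr(cells, function(breed, antigen_group, coated_antigen, day) {
    vacc <- serology$od450[serology$breed == breed &
                           serology$antigen_group == antigen_group &
                           serology$coated_antigen == coated_antigen &
                           serology$day == day]
    ctrl <- serology$od450[serology$breed == breed &
                           serology$antigen_group == control_group &
                           serology$coated_antigen == coated_antigen &
                           serology$day == day]
    if (length(ctrl) == 0) {
      rlang::abort(paste0("missing control group for ", breed, " / ",
                          coated_antigen, " / day ", day))
    }
    fit <- oneway_anova(list(vacc, ctrl))
    tibble::tibble(
      breed = breed, antigen_group = antigen_group,
      coated_antigen = coated_antigen, day = day,
      n_vaccinated = length(vacc), n_control = length(ctrl),
      statistic = fit$statistic, p_value = fit$p_value,
      signif_label = dplyr::case_when(
        fit$p_value < alpha / 10 ~ "**",
        fit$p_value < alpha ~ "*",
        TRUE ~ ""))
  })
}

#' Parameters significantly affected by at least k formulations
#'
#' The selection rule for the titer-outcome correlation: within each
#' (breed, tick species), a stage parameter is eligible when it was
#' significantly affected under at least `min_formulations` of the vaccine
#' formulations.
#'
#' @param reductions Gated reduction table (e.g. from [gate_stage_records()]
#'   or [reference_reductions()]) with `antigen_group`, `breed`,
#'   `tick_species`, `parameter`, `included`.
#' @param min_formulations Minimum number of formulations (default 3).
#' @return Tibble of eligible `(breed, tick_species, parameter)` rows with
#'   `n_formulations_significant`.
#' @export
eligible_parameters <- function(reductions, min_formulations = 3) {
  tibble::as_tibble(reductions) |>
    dplyr::group_by(.data$breed, .data$tick_species, .data$parameter) |>
    dplyr::summarise(
      n_formulations_significant = sum(.data$included, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$n_formulations_significant >= min_formulations)
}

#' Correlate day-60 antibody titers with per-animal stage outcomes
#'
#' Pools the individual animals of all vaccine formulations *and* the control
#' group (n = 20 in the default design: 4 animals x 5 groups) and computes,
#' per stage parameter, Spearman's rho between each animal's day-60 OD450
#' titer and its raw stage measurement (count, molting proportion or mass).
#' A protective association appears as a *negative* correlation (higher
#' titer, fewer/lighter ticks); `significant_negative` flags
#' `rho < 0 & p <= alpha`.
#'
#' @param titers Tibble with one row per animal: `animal_id`, `od450`.
#' @param stage_values Long tibble of per-animal values: `animal_id`,
#'   `parameter`, `value` (see [animal_stage_values()]).
#' @param reductions Optional gated reduction table; when supplied, each
#'   parameter's `mean_reduction_pct` is the mean of its included group-level
#'   reductions across formulations (0-reduction when never included).
#' @param alpha Significance level (inclusive, `p <= alpha`).
#' @param expected_n Expected pooled animal count; a differing count raises a
#'   warning, not an error.
#' @return Tibble with one row per parameter: `parameter`, `n`, `rho`,
#'   `p_value`, `mean_reduction_pct` (`NA` without `reductions`),
#'   `significant_negative`.
#' @export
correlate_titers_stages <- function(titers, stage_values, reductions = NULL,
                                    alpha = 0.05, expected_n = 20) {
  titers <- tibble::as_tibble(titers)
  stage_values <- tibble::as_tibble(stage_values)
  joined <- dplyr::inner_join(stage_values, titers, by = "animal_id")
  if (nrow(joined) == 0) rlang::abort("no overlapping animals")
  mean_red <- NULL
  if (!is.null(reductions)) {
    mean_red <- tibble::as_tibble(reductions) |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(mean_reduction_pct = mean(
        ifelse(.data$included, .data$reduction_pct, 0)), .groups = "drop")
  }
  out <- joined |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (!is.null(expected_n) && n != expected_n) {
        rlang::warn(paste0("parameter ", key$parameter, ": pooled n = ", n,
                           ", expected ", expected_n))
      }
      if (stats::var(df$od450) == 0) {
        rlang::abort("correlation undefined: constant titers")
      }
      fit <- spearman_rho(df$od450, df$value)
      tibble::tibble(n = n, rho = fit$estimate, p_value = fit$p_value)
    }) |>
    dplyr::ungroup()
  if (!is.null(mean_red)) {
    out <- dplyr::left_join(out, mean_red, by = "parameter")
  } else {
    out$mean_reduction_pct <- NA_real_
  }
  dplyr::mutate(out,
    significant_negative = .data$rho < 0 & .data$p_value <= alpha)
}

#' Reduction threshold for a significant titer-outcome correlation
#'
#' Scans correlation outcomes ordered by their mean stage reduction and
#' returns the smallest mean reduction at which a significant negative
#' titer-outcome correlation was observed. The threshold is *separating* when
#' every outcome with a larger-or-equal mean reduction is also significant
#' (equivalently: no non-significant outcome sits at or above it); an
#' imperfect separation returns the same minimum flagged `separating =
#' FALSE`. With no significant outcome the threshold is undefined (`NA`).
#'
#' @param outcomes Tibble from [correlate_titers_stages()] with
#'   `mean_reduction_pct` and `significant_negative`.
#' @return One-row tibble: `threshold_pct`, `separating`, `n_significant`.
#' @export
reduction_threshold <- function(outcomes) {
  outcomes <- tibble::as_tibble(outcomes)
  for (col in c("mean_reduction_pct", "significant_negative")) {
    if (!col %in% names(outcomes)) {
      rlang::abort(paste0("reduction_threshold() requires `", col, "`"))
    }
  }
  sig <- outcomes$significant_negative
  if (!any(sig)) {
    return(tibble::tibble(threshold_pct = NA_real_, separating = NA,
                          n_significant = 0L))
  }
  threshold <- min(outcomes$mean_reduction_pct[sig])
  separating <- !any(!sig & outcomes$mean_reduction_pct >= threshold)
  tibble::tibble(threshold_pct = threshold, separating = separating,
                 n_significant = sum(sig))
}
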