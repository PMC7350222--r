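#' Round half away from zero
#'
#' Commercial rounding used for report display: exact halves move away from
#' zero (so 0.5 -> 1, -0.5 -> -1), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

default_group_cols <- c("antigen_group", "breed", "tick_species")

group_cols_of <- function(data, by = NULL) {
  if (!is.null(by)) {
    missing <- setdiff(by, names(data))
    if (length(missing) > 0) {
      rlang::abort(paste0("grouping column(s) not found: ",
                          paste(missing, collapse = ", ")))
    }
    return(by)
  }
  intersect(default_group_cols, names(data))
}

#' Per-stage percent reduction in vaccinated versus control groups
#'
#' Computes, for each row, the percent reduction
#' `100 * (1 - vaccinated_value / control_value)`. The same survival-ratio
#' formula applies to all three measurement classes; only the quantity supplied
#' differs (pooled engorged-tick counts, molting proportions, or mass ratios).
#' Reductions may be negative when the vaccinated group outperforms the
#' control, and are capped above by 100 (total elimination).
#'
#' @param data A data frame with numeric columns `vaccinated_value` and
#'   `control_value`; any other columns (parameter codes, group labels) are
#'   passed through.
#' @return The input tibble with an added `reduction_pct` column.
#' @examples
#' stage_reduction(tibble::tibble(
#'   parameter = c("DL", "DN"),
#'   vaccinated_value = c(83, 0),
#'   control_value = c(100, 120)
#' ))
#' @export
stage_reduction <- function(data) {
  data <- tibble::as_tibble(data)
  for (col in c("vaccinated_value", "control_value")) {
    if (!col %in% names(data)) {
      rlang::abort(paste0("stage_reduction() requires a `", col, "` column"))
    }
  }
  bad <- which(data$vaccinated_value < 0 | data$control_value < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("negative stage values at row(s): ",
                        paste(bad, collapse = ", ")))
  }
  zero <- which(data$control_value == 0)
  if (length(zero) > 0) {
    rlang::abort(paste0(
      "reduction undefined: control_value is 0 at row(s) ",
      paste(zero, collapse = ", "),
      " (degenerate control group)"
    ))
  }
  dplyr::mutate(data,
    reduction_pct = 100 * (1 - .data$vaccinated_value / .data$control_value))
}

#' Significance-gated cumulative vaccine efficacy
#'
#' Combines per-stage reductions into the cumulative life-cycle efficacy
#' `E = 100 * (1 - prod(1 - D/100))`, where the product runs over *included*
#' parameters only: each included stage contributes its survival fraction
#' `1 - D/100`, excluded (non-significant) stages contribute a factor of 1.
#' With no included parameter the product is empty and `E = 0`.
#'
#' Inclusion follows the gating rule: a parameter enters the product only when
#' its vaccinated-vs-control difference is statistically significant. If the
#' data carry an `included` column it is used as-is; otherwise inclusion is
#' derived as `significant & reduction_pct > 0` (negative reductions -- a
#' vaccine making things worse -- are never auto-included; set
#' `include_negative = TRUE` to let significant negative reductions enter,
#' which can drive `E` below zero).
#'
#' @param data A data frame with one row per (group, parameter):
#'   `reduction_pct`, plus `included` and/or `significant` logical columns,
#'   and any group label columns.
#' @param by Character vector of grouping columns; defaults to whichever of
#'   `antigen_group`, `breed`, `tick_species` are present (no grouping columns
#'   means the whole table is one group).
#' @param printed_integers If `TRUE`, reductions are first rounded
#'   (half away from zero) to integer percent, reproducing published tables
#'   that print integer reductions.
#' @param include_negative Allow significant negative reductions into the
#'   product when deriving inclusion from `significant`.
#' @return A tibble with one row per group: the grouping columns,
#'   `n_included`, `efficacy_pct` (unrounded) and `efficacy_round`
#'   (integer percent, half away from zero).
#' @examples
#' vaccine_efficacy(tibble::tibble(
#'   reduction_pct = c(17, 22, 13, 19, 6),
#'   included = c(TRUE, TRUE, TRUE, FALSE, TRUE)
#' ))
#' @export
vaccine_efficacy <- function(data, by = NULL, printed_integers = FALSE,
                             include_negative = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"reduction_pct" %in% names(data)) {
    rlang::abort("vaccine_efficacy() requires a `reduction_pct` column")
  }
  if (!"included" %in% names(data)) {
    if (!"significant" %in% names(data)) {
      rlang::abort(
        "vaccine_efficacy() needs an `included` or `significant` column")
    }
    data$included <- data$significant &
      (include_negative | data$reduction_pct > 0)
  }
  data$included[is.na(data$included)] <- FALSE
  over <- which(data$included & data$reduction_pct > 100)
  if (length(over) > 0) {
    rlang::abort(paste0("included reduction_pct > 100 at row(s): ",
                        paste(over, collapse = ", ")))
  }
  if (printed_integers) {
    data$reduction_pct <- round_half_up(data$reduction_pct)
  }
  cols <- group_cols_of(data, by)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(
      n_included = sum(.data$included),
      efficacy_pct = 100 * (1 - prod(1 - .data$reduction_pct[.data$included] / 100)),
      .groups = "drop"
    ) |>
    dplyr::mutate(efficacy_round = round_half_up(.data$efficacy_pct))
}

#' Count tick developmental stages affected by vaccination
#'
#' Stage-coverage accounting: within each grouping (by antigen formulation,
#' tick species or cattle breed) counts how many of the observable stage
#' parameters were significantly affected (`included = TRUE`) out of how many
#' were observable. Denominators follow from the design: each three-host
#' (formulation, breed, species) group contributes 7 observable parameters,
#' each one-host group 3 (only the rows actually observable appear in the
#' table, so denominators are row counts).
#'
#' @param data Long per-parameter table (one row per group x parameter) with
#'   an `included` logical column and group label columns; a one-host group
#'   carries only its three observable parameter rows.
#' @param by Grouping column(s), e.g. `"antigen_group"` (default), or
#'   `"tick_species"`, `"breed"`.
#' @param early_stages If `TRUE`, restrict to the early three-host parameters
#'   DL and DMn before counting (denominator 8 per antigen in the two-breed,
#'   two-three-host-species design).
#' @param check_factorial Validate that every antigen formulation covers the
#'   same (breed, species, parameter) cells; missing cells raise an error
#'   listing them.
#' @return A tibble with the grouping columns, `n_affected`, `n_possible` and
#'   `proportion`.
#' @export
count_affected_stages <- function(data, by = "antigen_group",
                                  early_stages = FALSE,
                                  check_factorial = TRUE) {
  data <- tibble::as_tibble(data)
  for (col in c("included", "parameter")) {
    if (!col %in% names(data)) {
      rlang::abort(paste0("count_affected_stages() requires a `", col,
                          "` column"))
    }
  }
  if (check_factorial && all(default_group_cols %in% names(data))) {
    cells <- dplyr::distinct(data, .data$breed, .data$tick_species,
                             .data$parameter)
    expected <- tidyr::crossing(
      antigen_group = unique(data$antigen_group), cells)
    missing <- dplyr::anti_join(
      expected, data, by = c("antigen_group", "breed", "tick_species",
                             "parameter"))
    if (nrow(missing) > 0) {
      cells_txt <- paste(missing$antigen_group, missing$breed,
                         missing$tick_species, missing$parameter,
                         sep = "/", collapse = "; ")
      rlang::abort(paste0("inconsistent factorial design; missing cells: ",
                          cells_txt))
    }
  }
  if (early_stages) {
    data <- dplyr::filter(data, .data$parameter %in% c("DL", "DMn"))
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_affected = sum(.data$included, na.rm = TRUE),
      n_possible = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(proportion = .data$n_affected / .data$n_possible)
}

#' Mean cumulative efficacy per antigen formulation
#'
#' Arithmetic mean of the group-level efficacy values over all
#' (breed, tick species) cells of each antigen formulation.
#'
#' @param efficacy Output of [vaccine_efficacy()]: one row per group with
#'   `antigen_group` and `efficacy_pct` (uses `efficacy_round` when
#'   `printed_integers = TRUE`).
#' @param printed_integers Average the integer-rounded group efficacies
#'   instead of the unrounded values.
#' @return A tibble with `antigen_group`, `n_groups`, `mean_efficacy_pct` and
#'   `mean_efficacy_round`.
#' @export
total_efficacy_by_antigen <- function(efficacy, printed_integers = FALSE) {
  efficacy <- tibble::as_tibble(efficacy)
  if (!"antigen_group" %in% names(efficacy)) {
    rlang::abort("total_efficacy_by_antigen() requires `antigen_group`")
  }
  if (nrow(efficacy) == 0) {
    rlang::abort("no efficacy results supplied")
  }
  value <- if (printed_integers) efficacy$efficacy_round else efficacy$efficacy_pct
  efficacy$.value <- value
  efficacy |>
    dplyr::group_by(.data$antigen_group) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      mean_efficacy_pct = mean(.data$.value),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_efficacy_round = round_half_up(.data$mean_efficacy_pct))
}
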