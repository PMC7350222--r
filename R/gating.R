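# per-animal value of one stage parameter (used by the rank gate and the
# titer correlation, which both operate on individual animals)
animal_parameter_values <- function(records, parameter) {
  switch(parameter,
    DL  = records$larvae_engorged,
    DN  = records$nymphs_engorged,
    DA  = records$females_engorged,
    DMn = ifelse(records$larvae_engorged > 0,
                 records$larvae_molted / records$larvae_engorged, NA_real_),
    DMa = ifelse(records$nymphs_engorged > 0,
                 records$nymphs_molted / records$nymphs_engorged, NA_real_),
    DO  = ifelse(records$females_engorged > 0,
                 records$egg_mass_g / records$females_engorged, NA_real_),
    DF  = records$larval_mass_per_g_eggs_g,
    rlang::abort(paste0("unknown stage parameter: ", parameter))
  )
}

#' Per-animal stage parameter values
#'
#' Expands per-animal tick records into a long table of raw per-animal values
#' of each observable stage parameter: engorged counts for DL/DN/DA, molting
#' proportions for DMn/DMa, egg mass per engorged female for DO and larval
#' mass per gram of eggs for DF. These raw values (not group-level
#' reductions) are what the titer-outcome correlation operates on.
#'
#' @param records Per-animal record tibble (see [read_stage_records()]).
#' @return Long tibble: identifying columns plus `parameter` and `value`;
#'   parameters that are unobservable for a record (one-host species, or a
#'   zero denominator) are dropped.
#' @export
animal_stage_values <- function(records) {
  records <- tibble::as_tibble(records)
  id_cols <- intersect(c("animal_id", "breed", "antigen_group",
                         "tick_species"), names(records))
  purrr::map_dfr(stage_parameter_levels(), function(par) {
    vals <- animal_parameter_values(records, par)
    out <- records[id_cols]
    out$parameter <- par
    out$value <- vals
    out[!is.na(out$value), ]
  })
}

# group-level measured quantity per stage class: pooled totals for counts,
# pooled proportions for molting, pooled mass ratios for oviposition/fertility
group_parameter_value <- function(records, parameter) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  switch(parameter,
    DL  = sum(records$larvae_engorged),
    DN  = sum(records$nymphs_engorged),
    DA  = sum(records$females_engorged),
    DMn = ratio(sum(records$larvae_molted), sum(records$larvae_engorged)),
    DMa = ratio(sum(records$nymphs_molted), sum(records$nymphs_engorged)),
    DO  = ratio(sum(records$egg_mass_g), sum(records$females_engorged)),
    DF  = ratio(sum(records$larval_mass_per_g_eggs_g * records$egg_mass_g),
                sum(records$egg_mass_g)),
    rlang::abort(paste0("unknown stage parameter: ", parameter))
  )
}

#' Group-level stage summaries for each vaccinated arm versus its control
#'
#' Pairs every vaccinated (antigen formulation, breed, tick species) arm with
#' the matching control arm and computes, per observable stage parameter, the
#' group-level measured quantities that feed the reduction formulae: pooled
#' engorged-tick totals (counts), pooled molting proportions, egg mass per
#' engorged female, and larval mass per gram of eggs (egg-mass-weighted across
#' animals).
#'
#' @param records Per-animal record tibble.
#' @param control_group Label of the control arm in `antigen_group`.
#' @return Tibble with `antigen_group`, `breed`, `tick_species`, `parameter`,
#'   `stage_class`, `vaccinated_value`, `control_value`, `n_vaccinated`,
#'   `n_control`.
#' @export
summarise_stage_groups <- function(records, control_group = "control") {
  records <- tibble::as_tibble(records)
  cells <- records |>
    dplyr::filter(.data$antigen_group != control_group) |>
    dplyr::distinct(.data$antigen_group, .data$breed, .data$tick_species)
  purrr::pmap_dfr(cells, function(antigen_group, breed, tick_species) {
    vacc <- dplyr::filter(records, .data$antigen_group == .env$antigen_group,
                          .data$breed == .env$breed,
                          .data$tick_species == .env$tick_species)
    ctrl <- dplyr::filter(records, .data$antigen_group == control_group,
                          .data$breed == .env$breed,
                          .data$tick_species == .env$tick_species)
    if (nrow(ctrl) == 0) {
      rlang::abort(paste0("no control arm for ", breed, " / ", tick_species))
    }
    one_host <- all(is.na(vacc$larvae_applied))
    pars <- applicable_parameters(one_host)
    tibble::tibble(
      antigen_group = antigen_group, breed = breed,
      tick_species = tick_species, parameter = pars,
      stage_class = stage_class_of(pars),
      vaccinated_value = vapply(pars, function(p)
        group_parameter_value(vacc, p), numeric(1), USE.NAMES = FALSE),
      control_value = vapply(pars, function(p)
        group_parameter_value(ctrl, p), numeric(1), USE.NAMES = FALSE),
      n_vaccinated = nrow(vacc), n_control = nrow(ctrl)
    )
  })
}

#' Gate and estimate all stage reductions from per-animal records
#'
#' The core group-level analysis: for every vaccinated arm and observable
#' stage parameter, computes the percent reduction relative to the matching
#' control arm and the gating test (see [chi_square_gate()]), and derives the
#' inclusion flag (`significant` and positive, unless `include_negative`).
#'
#' @param records Per-animal record tibble.
#' @param config A [gate_config()].
#' @param control_group Label of the control arm.
#' @param include_negative Let significant negative reductions be included.
#' @return Tibble with one row per (group, parameter): group labels,
#'   `parameter`, `vaccinated_value`, `control_value`, `reduction_pct`,
#'   `statistic`, `p_value`, `significant`, `small_sample`, `included`.
#' @export
gate_stage_records <- function(records, config = gate_config(),
                               control_group = "control",
                               include_negative = FALSE) {
  records <- tibble::as_tibble(records)
  summaries <- summarise_stage_groups(records, control_group)
  reductions <- stage_reduction(summaries)
  tests <- purrr::pmap_dfr(
    reductions[c("antigen_group", "breed", "tick_species", "parameter")],
    function(antigen_group, breed, tick_species, parameter) {
      vacc <- dplyr::filter(records,
        .data$antigen_group == .env$antigen_group, .data$breed == .env$breed,
        .data$tick_species == .env$tick_species)
      ctrl <- dplyr::filter(records,
        .data$antigen_group == control_group, .data$breed == .env$breed,
        .data$tick_species == .env$tick_species)
      chi_square_gate(vacc, ctrl, parameter, config)
    })
  out <- dplyr::bind_cols(
    reductions,
    tests[c("statistic", "p_value", "significant", "small_sample")])
  out$significant[is.na(out$significant)] <- FALSE
  out$included <- out$significant &
    (include_negative | out$reduction_pct > 0)
  out
}
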