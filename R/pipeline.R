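#' Run the full trial analysis pipeline
#'
#' End-to-end analysis of a vaccination trial, from per-animal records to the
#' final efficacy report: gated stage reductions per (formulation, breed,
#' tick species) group, cumulative efficacy, stage-coverage counts, mean
#' efficacy per antigen, a breed comparison of total efficacy (Welch's t per
#' formulation over its per-species efficacies), the antibody time-course
#' tests, the pooled titer-outcome correlations for the eligible parameters
#' of each Rhipicephalus group, and the reduction threshold. Inputs may be a
#' simulated trial, explicit tables, or CSV paths.
#'
#' @param stage_records Per-animal record tibble, a CSV path, or `NULL` to
#'   simulate from `config` with `seed`.
#' @param serology Serology tibble, CSV path, or `NULL` (taken from the
#'   simulation when records are simulated; antibody analyses are skipped
#'   when absent).
#' @param config A [trial_config()] (design and simulation settings).
#' @param gate A [gate_config()] (alpha, gating method).
#' @param seed Seed for simulation (defaults to `config$seed`).
#' @param correlation_coated Coated antigen whose day-60 titers feed the
#'   correlation analysis.
#' @param correlation_species Tick species included in the titer-outcome
#'   correlation (the Rhipicephalus species by default).
#' @param include_negative Passed to [gate_stage_records()].
#' @return A list of class `tickvax_analysis` with elements `reductions`,
#'   `efficacy`, `coverage`, `coverage_early`, `antigen_totals`,
#'   `breed_comparison`, `timecourse`, `correlations`, `threshold`,
#'   `manifest`.
#' @examples
#' \donttest{
#' fit <- run_pipeline(config = trial_config(), seed = 42)
#' fit$efficacy
#' }
#' @export
run_pipeline <- function(stage_records = NULL, serology = NULL,
                         config = trial_config(), gate = gate_config(),
                         seed = config$seed,
                         correlation_coated = "Rappendiculatus_SUB",
                         correlation_species = c("Rappendiculatus",
                                                 "Rdecoloratus"),
                         include_negative = FALSE) {
  files <- character(0)
  if (is.character(stage_records)) {
    files["stage_records"] <- stage_records
    stage_records <- read_stage_records(stage_records)
  }
  if (is.character(serology)) {
    files["serology"] <- serology
    serology <- read_serology(serology)
  }
  if (is.null(stage_records)) {
    trial <- simulate_trial(config, seed = seed)
    stage_records <- trial$stage_records
    if (is.null(serology)) serology <- trial$serology
  }
  reductions <- gate_stage_records(stage_records, config = gate,
                                   control_group = config$control_group,
                                   include_negative = include_negative)
  efficacy <- vaccine_efficacy(reductions)
  coverage <- count_affected_stages(reductions, by = "antigen_group")
  coverage_early <- count_affected_stages(reductions, by = "antigen_group",
                                          early_stages = TRUE)
  antigen_totals <- total_efficacy_by_antigen(efficacy)
  breed_comparison <- breed_efficacy_comparison(efficacy)
  timecourse <- NULL; correlations <- NULL; threshold <- NULL
  if (!is.null(serology) && nrow(serology) > 0) {
    timecourse <- titer_timecourse_test(serology, alpha = gate$alpha,
                                        control_group = config$control_group)
    day60 <- serology |>
      dplyr::filter(.data$day == 60,
                    .data$coated_antigen == correlation_coated) |>
      dplyr::select("animal_id", "breed", "od450")
    eligible <- eligible_parameters(reductions)
    cells <- stage_records |>
      dplyr::filter(.data$tick_species %in% correlation_species) |>
      dplyr::distinct(.data$breed, .data$tick_species)
    correlations <- purrr::pmap_dfr(cells, function(breed, tick_species) {
      elig <- eligible$parameter[eligible$breed == breed &
                                 eligible$tick_species == tick_species]
      if (length(elig) == 0) return(tibble::tibble())
      recs <- dplyr::filter(stage_records, .data$breed == .env$breed,
                            .data$tick_species == .env$tick_species)
      values <- animal_stage_values(recs) |>
        dplyr::filter(.data$parameter %in% elig) |>
        dplyr::select("animal_id", "parameter", "value")
      red <- dplyr::filter(reductions, .data$breed == .env$breed,
                           .data$tick_species == .env$tick_species,
                           .data$parameter %in% elig)
      titers <- day60[day60$breed == breed, c("animal_id", "od450")]
      out <- correlate_titers_stages(
        titers, values, reductions = red, alpha = gate$alpha,
        expected_n = length(unique(titers$animal_id)))
      dplyr::bind_cols(tibble::tibble(breed = breed,
                                      tick_species = tick_species), out)
    })
    if (nrow(correlations) > 0) {
      threshold <- reduction_threshold(correlations)
    }
  }
  structure(list(
    reductions = reductions, efficacy = efficacy, coverage = coverage,
    coverage_early = coverage_early, antigen_totals = antigen_totals,
    breed_comparison = breed_comparison, timecourse = timecourse,
    correlations = correlations, threshold = threshold,
    manifest = run_manifest(config, gate, seed, files)),
    class = "tickvax_analysis")
}

#' Compare total efficacy between breeds
#'
#' For each antigen formulation, compares the per-(tick species) group
#' efficacies of the two breeds with Welch's unequal-variance t test
#' (n = 2 vs 3 species in the default design).
#'
#' @param efficacy Output of [vaccine_efficacy()] with `antigen_group`,
#'   `breed`, `efficacy_pct`.
#' @return Tibble with one row per formulation: means per breed, `statistic`,
#'   `p_value`, `df`.
#' @export
breed_efficacy_comparison <- function(efficacy) {
  efficacy <- tibble::as_tibble(efficacy)
  breeds <- unique(efficacy$breed)
  if (length(breeds) != 2) {
    return(tibble::tibble())
  }
  efficacy |>
    dplyr::group_by(.data$antigen_group) |>
    dplyr::group_modify(function(df, key) {
      a <- df$efficacy_pct[df$breed == breeds[1]]
      b <- df$efficacy_pct[df$breed == breeds[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                              statistic = NA_real_, p_value = NA_real_,
                              df = NA_real_))
      }
      fit <- welch_t(a, b)
      tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                     statistic = fit$statistic, p_value = fit$p_value,
                     df = fit$df)
    }) |>
    dplyr::ungroup() |>
    (function(out) {
      names(out)[names(out) == "mean_a"] <- paste0("mean_", breeds[1])
      names(out)[names(out) == "mean_b"] <- paste0("mean_", breeds[2])
      out
    })()
}

#' @export
print.tickvax_analysis <- function(x, ...) {
  cat("<tickvax_analysis>\n")
  cat("  groups analysed: ", nrow(x$efficacy), "\n", sep = "")
  cat("  efficacy range:  ",
      paste(round_half_up(range(x$efficacy$efficacy_pct)), collapse = " - "),
      "%\n", sep = "")
  cat("  stages included: ", sum(x$reductions$included), "/",
      nrow(x$reductions), "\n", sep = "")
  if (!is.null(x$threshold) && !is.na(x$threshold$threshold_pct)) {
    cat("  correlation threshold: ",
        round_half_up(x$threshold$threshold_pct, 1), "% (",
        if (isTRUE(x$threshold$separating)) "separating" else
          "non-separating", ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy an analysis into one of its component tables
#'
#' @param x A `tickvax_analysis`.
#' @param table Which component to return: `"reductions"`, `"efficacy"`
#'   (default), `"coverage"`, `"coverage_early"`, `"antigen_totals"`,
#'   `"breed_comparison"`, `"timecourse"`, `"correlations"`, `"threshold"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy tickvax_analysis
#' @export
tidy.tickvax_analysis <- function(x, table = "efficacy", ...) {
  choices <- c("reductions", "efficacy", "coverage", "coverage_early",
               "antigen_totals", "breed_comparison", "timecourse",
               "correlations", "threshold")
  table <- match.arg(table, choices)
  out <- x[[table]]
  if (is.null(out)) {
    rlang::abort(paste0("analysis has no `", table,
                        "` component (serology absent?)"))
  }
  tibble::as_tibble(out)
}

#' One-row summary of a trial analysis
#'
#' @param x A `tickvax_analysis`.
#' @param ... Unused.
#' @return One-row tibble: group count, efficacy range and mean, number of
#'   included stage parameters, correlation threshold (if computed).
#' @method glance tickvax_analysis
#' @export
glance.tickvax_analysis <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$efficacy),
    min_efficacy_pct = min(x$efficacy$efficacy_pct),
    max_efficacy_pct = max(x$efficacy$efficacy_pct),
    mean_efficacy_pct = mean(x$efficacy$efficacy_pct),
    n_stages_included = sum(x$reductions$included),
    n_stages_possible = nrow(x$reductions),
    threshold_pct = if (!is.null(x$threshold)) x$threshold$threshold_pct
                    else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
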