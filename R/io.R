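stage_record_columns <- c(
  "animal_id", "breed", "antigen_group", "tick_species",
  "larvae_applied", "larvae_engorged", "larvae_molted",
  "nymphs_applied", "nymphs_engorged", "nymphs_molted",
  "females_applied", "females_engorged",
  "egg_mass_g", "larval_mass_per_g_eggs_g")

serology_columns <- c("animal_id", "breed", "antigen_group",
                      "coated_antigen", "day", "od450")

check_chain <- function(records) {
  viol <- function(a, b) which(!is.na(records[[a]]) & !is.na(records[[b]]) &
                                 records[[b]] > records[[a]])
  bad <- sort(unique(c(
    viol("larvae_applied", "larvae_engorged"),
    viol("larvae_engorged", "larvae_molted"),
    viol("nymphs_applied", "nymphs_engorged"),
    viol("nymphs_engorged", "nymphs_molted"),
    viol("females_applied", "females_engorged"))))
  neg <- which(apply(
    records[setdiff(stage_record_columns,
                    c("animal_id", "breed", "antigen_group",
                      "tick_species"))], 1,
    function(r) any(!is.na(r) & r < 0)))
  if (length(neg) > 0) {
    rlang::abort(paste0("negative stage values at row(s): ",
                        paste(neg, collapse = ", ")))
  }
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "stage-chain violations (engorged > applied or molted > engorged) ",
      "at row(s): ", paste(bad, collapse = ", ")))
  }
  invisible(records)
}

#' Read per-animal tick stage records
#'
#' Reads the stage-record CSV schema (one row per animal x tick species) and
#' validates it: all columns present and numeric where expected, and the
#' life-stage chain consistent (engorged <= applied, molted <= engorged) --
#' violations are reported with their row numbers. One-host species leave the
#' larval and nymphal fields empty.
#'
#' @param path CSV file path.
#' @return Tibble of validated records.
#' @export
read_stage_records <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE,
                             progress = FALSE)
  if (nrow(records) == 0) {
    rlang::warn(paste0("empty stage-record file: ", path))
    records <- tibble::as_tibble(
      stats::setNames(rep(list(numeric(0)), length(stage_record_columns)),
                      stage_record_columns))
    records$animal_id <- character(0); records$breed <- character(0)
    records$antigen_group <- character(0)
    records$tick_species <- character(0)
    return(records)
  }
  missing <- setdiff(stage_record_columns, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("stage-record file lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  num_cols <- setdiff(stage_record_columns,
                      c("animal_id", "breed", "antigen_group",
                        "tick_species"))
  for (col in num_cols) {
    if (!is.numeric(records[[col]])) {
      rlang::abort(paste0("non-numeric values in column `", col, "`"))
    }
  }
  check_chain(records)
  records[stage_record_columns]
}

#' Write per-animal tick stage records
#' @param records Stage-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_records <- function(records, path) {
  readr::write_csv(records[stage_record_columns], path, progress = FALSE)
  invisible(path)
}

#' Read an ELISA serology table
#'
#' @param path CSV with columns `animal_id`, `breed`, `antigen_group`,
#'   `coated_antigen`, `day`, `od450`.
#' @return Tibble of validated readings (OD450 must be non-negative).
#' @export
read_serology <- function(path) {
  serology <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(serology_columns, names(serology))
  if (length(missing) > 0) {
    rlang::abort(paste0("serology file lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!is.numeric(serology$od450) || !is.numeric(serology$day)) {
    rlang::abort("`day` and `od450` must be numeric")
  }
  bad <- which(serology$od450 < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("negative OD450 at row(s): ",
                        paste(bad, collapse = ", ")))
  }
  serology[serology_columns]
}

#' Write an ELISA serology table
#' @param serology Serology tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_serology <- function(serology, path) {
  readr::write_csv(serology[serology_columns], path, progress = FALSE)
  invisible(path)
}

#' Run manifest for a pipeline execution
#'
#' Captures everything needed to replay an analysis: a hash of the
#' configuration, the seed, the gating settings and digests of any input
#' files.
#'
#' @param config A [trial_config()].
#' @param gate A [gate_config()].
#' @param seed Seed used.
#' @param files Named character vector of input file paths (optional).
#' @return A list of class `tickvax_manifest`.
#' @export
run_manifest <- function(config, gate = gate_config(), seed = NULL,
                         files = character(0)) {
  digests <- vapply(files, function(f)
    rlang::hash(readr::read_file(f)), character(1))
  structure(list(
    config_hash = rlang::hash(config),
    gate = list(alpha = gate$alpha, gate_method = gate$gate_method,
                mass_unit_scale = gate$mass_unit_scale),
    seed = seed,
    input_digests = digests,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "tickvax_manifest")
}
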