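#' Format a publication-style trial report table
#'
#' Renders gated reductions and cumulative efficacies as the conventional
#' trial summary table: one block per antigen formulation, rows grouped by
#' breed then tick species, one column per stage parameter (DL ... DF) plus
#' the cumulative efficacy E. Significant parameters are starred; one-host
#' species leave the larval and nymphal columns blank; negative reductions
#' are rendered with their sign and flagged in a footnote as excluded.
#'
#' @param reductions Long gated reduction table (`antigen_group`, `breed`,
#'   `tick_species`, `parameter`, `reduction_pct`, `significant`,
#'   `included`).
#' @param efficacy Optional matching output of [vaccine_efficacy()];
#'   computed from `reductions` when omitted.
#' @param printed_integers Use integer-rounded reductions for both display
#'   and the efficacy product.
#' @return Character vector of report lines.
#' @export
format_trial_report <- function(reductions, efficacy = NULL,
                                printed_integers = FALSE) {
  reductions <- tibble::as_tibble(reductions)
  header <- c("Results of the vaccination trials",
              strrep("=", 70))
  if (nrow(reductions) == 0) {
    return(c(header, "(no results)"))
  }
  if (is.null(efficacy)) {
    efficacy <- vaccine_efficacy(reductions,
                                 printed_integers = printed_integers)
  }
  pars <- stage_parameter_levels()
  widths <- c(group = 18, par = 7, e = 6)
  fmt_cell <- function(value, star) {
    if (is.na(value)) return("")
    paste0(round_half_up(value), "%", if (isTRUE(star)) "*" else "")
  }
  pad <- function(x, w) formatC(x, width = -w)
  lines <- header
  any_negative <- any(reductions$reduction_pct < 0, na.rm = TRUE)
  for (antigen in unique(reductions$antigen_group)) {
    lines <- c(lines, "", paste0("Vaccination with ", antigen),
               paste0(pad("Group", widths["group"]),
                      paste(vapply(pars, pad, "", w = widths["par"]),
                            collapse = ""),
                      "E"))
    block <- reductions[reductions$antigen_group == antigen, ]
    for (breed in unique(block$breed)) {
      lines <- c(lines, breed)
      sub <- block[block$breed == breed, ]
      for (species in unique(sub$tick_species)) {
        row <- sub[sub$tick_species == species, ]
        cells <- vapply(pars, function(p) {
          i <- match(p, row$parameter)
          if (is.na(i)) return("")
          val <- row$reduction_pct[i]
          if (printed_integers) val <- round_half_up(val)
          fmt_cell(val, row$significant[i])
        }, "")
        e <- efficacy[efficacy$antigen_group == antigen &
                      efficacy$breed == breed &
                      efficacy$tick_species == species, ]
        e_cell <- if (nrow(e) == 1) paste0(e$efficacy_round, "%") else ""
        lines <- c(lines, paste0(
          pad(paste0("  ", species), widths["group"]),
          paste(vapply(cells, pad, "", w = widths["par"]), collapse = ""),
          e_cell))
      }
    }
  }
  lines <- c(lines, "",
             paste0("E (%) = 100 (1 - product of (1 - D/100) over starred ",
                    "parameters); '*' marks a significant ",
                    "vaccinated-control difference."))
  if (any_negative) {
    lines <- c(lines,
               paste0("Negative reductions (vaccinated exceeding control) ",
                      "are shown with their sign and excluded from E."))
  }
  lines
}

#' Write a trial report to disk
#'
#' @param x A `tickvax_analysis`, or a gated reduction table.
#' @param path Output file path.
#' @param style `"text"` for the human-readable table,
#'   `"tsv"` for the machine-readable long table (reductions joined with
#'   group efficacy).
#' @param printed_integers Passed to [format_trial_report()].
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, style = c("text", "tsv"),
                         printed_integers = FALSE) {
  style <- match.arg(style)
  if (inherits(x, "tickvax_analysis")) {
    reductions <- x$reductions; efficacy <- x$efficacy
  } else {
    reductions <- tibble::as_tibble(x)
    efficacy <- if (nrow(reductions) > 0) {
      vaccine_efficacy(reductions, printed_integers = printed_integers)
    } else NULL
  }
  if (style == "text") {
    writeLines(format_trial_report(reductions, efficacy,
                                   printed_integers = printed_integers),
               path)
  } else {
    long <- reductions
    if (!is.null(efficacy)) {
      long <- dplyr::left_join(
        long, efficacy[c("antigen_group", "breed", "tick_species",
                         "efficacy_pct", "efficacy_round")],
        by = c("antigen_group", "breed", "tick_species"))
    }
    readr::write_tsv(long, path, progress = FALSE)
  }
  invisible(path)
}
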