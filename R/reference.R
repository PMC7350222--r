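#' Reference group-level reduction table from the SUB vaccination trials
#'
#' The published group-level summary of the two-breed, three-tick-species
#' subolesin (SUB) vaccination trials: for each of the 20 (antigen
#' formulation, cattle breed, tick species) groups, the printed integer
#' percent reduction of every observable stage parameter, its significance
#' star, and the reported cumulative efficacy. One-host groups
#' (R. decoloratus) carry only their three observable parameters (DA, DO,
#' DF); B. indicus cattle were not challenged with the one-host species.
#'
#' This table serves as a regression fixture for the efficacy calculations
#' (feed the starred integer reductions through the survival-fraction product
#' in printed-integer mode) and as the default effect-size map of the
#' synthetic trial generator.
#'
#' @return Long tibble, one row per (group, observable parameter):
#'   `antigen_group`, `breed`, `tick_species`, `parameter`, `reduction_pct`
#'   (printed integer percent), `significant` (the printed star),
#'   `included` (equal to `significant`; no starred negative entries occur)
#'   and `reported_efficacy_pct` (the printed cumulative efficacy of the
#'   group, repeated across its rows).
#' @examples
#' ref <- reference_reductions()
#' dplyr::count(ref, antigen_group)
#' @export
reference_reductions <- function() {
  # row order: DL, DMn, DN, DMa, DA, DO, DF (three-host) or DA, DO, DF
  # (one-host); stars encoded as negative entries would be, but none occur
  row3 <- function(antigen, breed, species, vals, stars, e) {
    tibble::tibble(
      antigen_group = antigen, breed = breed, tick_species = species,
      parameter = stage_parameter_levels(),
      reduction_pct = as.numeric(vals), significant = as.logical(stars),
      reported_efficacy_pct = e)
  }
  row1 <- function(antigen, breed, species, vals, stars, e) {
    tibble::tibble(
      antigen_group = antigen, breed = breed, tick_species = species,
      parameter = c("DA", "DO", "DF"),
      reduction_pct = as.numeric(vals), significant = as.logical(stars),
      reported_efficacy_pct = e)
  }
  rapp <- "Rappendiculatus_SUB"; avar <- "Avariegatum_SUB"
  rdec <- "Rdecoloratus_SUB"; comb <- "combined_SUB"
  bi <- "B_indicus"; cb <- "crossbred"
  RA <- "Rappendiculatus"; AV <- "Avariegatum"; RD <- "Rdecoloratus"
  out <- dplyr::bind_rows(
    row3(rapp, bi, RA, c(17, 22, 13, 0, 19, 6, 0),
         c(1, 1, 1, 0, 0, 1, 0), 47),
    row3(rapp, bi, AV, c(0, 25, 0, 3, 19, 31, 0),
         c(0, 1, 0, 1, 0, 1, 0), 50),
    row3(rapp, cb, RA, c(41, 64, 0, 0, 51, 0, 0),
         c(1, 1, 0, 0, 1, 0, 0), 90),
    row3(rapp, cb, AV, c(34, 44, 19, 25, 0, 4, 49),
         c(1, 1, 1, 1, 0, 1, 1), 89),
    row1(rapp, cb, RD, c(0, 8, 47), c(0, 1, 1), 51),

    row3(avar, bi, RA, c(61, 51, 0, 0, 29, 0, 0),
         c(1, 1, 0, 0, 1, 0, 0), 86),
    row3(avar, bi, AV, c(0, 1, 7, 3, 41, 0, 0),
         c(0, 1, 1, 1, 1, 0, 0), 47),
    row3(avar, cb, RA, c(53, 39, 0, 39, 0, 4, 0),
         c(1, 1, 0, 1, 0, 1, 0), 83),
    row3(avar, cb, AV, c(54, 28, 16, 0, 0, 14, 0),
         c(1, 1, 1, 0, 0, 1, 0), 76),
    row1(avar, cb, RD, c(0, 0, 72), c(0, 0, 1), 72),

    row3(rdec, bi, RA, c(0, 0, 25, 0, 55, 0, 0),
         c(0, 0, 1, 0, 1, 0, 0), 66),
    row3(rdec, bi, AV, c(0, 0, 32, 0, 38, 0, 0),
         c(0, 0, 1, 0, 1, 0, 0), 58),
    row3(rdec, cb, RA, c(62, 47, 25, 19, 0, 10, 0),
         c(1, 1, 1, 1, 0, 1, 0), 89),
    row3(rdec, cb, AV, c(69, 50, 19, 18, 0, 0, 39),
         c(1, 1, 1, 1, 0, 0, 1), 94),
    row1(rdec, cb, RD, c(0, 0, 69), c(0, 0, 1), 69),

    row3(comb, bi, RA, c(38, 53, 0, 0, 57, 0, 38),
         c(1, 1, 0, 0, 1, 0, 1), 92),
    row3(comb, bi, AV, c(0, 0, 0, 0, 51, 0, 0),
         c(0, 0, 0, 0, 1, 0, 0), 51),
    row3(comb, cb, RA, c(29, 53, 0, 22, 0, 0, 0),
         c(1, 1, 0, 1, 0, 0, 0), 74),
    row3(comb, cb, AV, c(27, 0, 7, 28, 0, 13, 0),
         c(1, 0, 1, 1, 0, 1, 0), 69),
    row1(comb, cb, RD, c(0, 0, 71), c(0, 0, 1), 71)
  )
  out$included <- out$significant
  out
}
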