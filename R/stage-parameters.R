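#' Tick life-stage reduction parameters
#'
#' The seven per-stage vaccine effect parameters tracked across the tick life
#' cycle. Three classes of measurement feed them: pooled counts of successfully
#' engorged ticks (`count`: DL, DN, DA), molting proportions (`molting`: DMn,
#' DMa) and mass ratios (`mass_ratio`: DO for egg mass per engorged female, DF
#' for larval mass per gram of eggs). The larval and nymphal parameters are
#' only observable for three-host tick species; one-host species, which
#' complete their development on a single animal, expose only DA, DO and DF.
#'
#' @return A tibble with one row per parameter and columns:
#' \describe{
#'   \item{parameter}{code, one of `DL`, `DMn`, `DN`, `DMa`, `DA`, `DO`, `DF`}
#'   \item{stage_class}{`count`, `molting` or `mass_ratio`}
#'   \item{host_cycle}{`three_host_only` or `all`}
#'   \item{description}{what the parameter measures}
#' }
#' @examples
#' stage_parameters()
#' @export
stage_parameters <- function() {
  tibble::tibble(
    parameter = c("DL", "DMn", "DN", "DMa", "DA", "DO", "DF"),
    stage_class = c("count", "molting", "count", "molting", "count",
                    "mass_ratio", "mass_ratio"),
    host_cycle = c("three_host_only", "three_host_only", "three_host_only",
                   "three_host_only", "all", "all", "all"),
    description = c(
      "reduction in number of engorged larvae",
      "reduction in larval molting success (larva to nymph)",
      "reduction in number of engorged nymphs",
      "reduction in nymphal molting success (nymph to adult)",
      "reduction in number of engorged adult female ticks",
      "reduction in oviposition (egg mass per engorged female)",
      "reduction in egg fertility (larval mass per gram of eggs)"
    )
  )
}

# canonical life-cycle ordering used by reports and reference tables
stage_parameter_levels <- function() {
  c("DL", "DMn", "DN", "DMa", "DA", "DO", "DF")
}

# parameters observable for a given host cycle
applicable_parameters <- function(one_host) {
  if (one_host) c("DA", "DO", "DF") else stage_parameter_levels()
}

#' @keywords internal
stage_class_of <- function(parameter) {
  sp <- stage_parameters()
  sp$stage_class[match(parameter, sp$parameter)]
}
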