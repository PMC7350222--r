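#' Gating configuration
#'
#' Settings for the per-parameter significance gate that decides which stage
#' reductions enter the cumulative efficacy product.
#'
#' @param alpha Significance level, strictly between 0 and 1. Gating uses the
#'   strict inequality `p < alpha`.
#' @param gate_method `"chi_square_pooled"` (default): Pearson chi-square,
#'   without continuity correction, on the 2x2 table of arm x outcome pooled
#'   over the animals of each arm; mass-ratio parameters are scaled to integer
#'   pseudo-counts first. `"rank_per_animal"`: exact Mann-Whitney test across
#'   the per-animal values of the two arms, statistically cleaner for the
#'   continuous mass parameters.
#' @param mass_unit_scale Units per gram used to convert masses to integer
#'   pseudo-counts under `chi_square_pooled` (default 1000, i.e. milligrams).
#' @return A list of class `tickvax_gate_config`.
#' @export
gate_config <- function(alpha = 0.05,
                        gate_method = c("chi_square_pooled", "rank_per_animal"),
                        mass_unit_scale = 1000) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be a single number strictly between 0 and 1")
  }
  if (!is.numeric(mass_unit_scale) || mass_unit_scale <= 0) {
    rlang::abort("mass_unit_scale must be positive")
  }
  structure(
    list(alpha = alpha,
         gate_method = match.arg(gate_method),
         mass_unit_scale = mass_unit_scale),
    class = "tickvax_gate_config"
  )
}

test_result <- function(statistic, p_value, df, method, ...) {
  tibble::tibble(statistic = statistic, p_value = p_value, df = df,
                 method = method, ...)
}

#' Welch's two-sample t test
#'
#' Unequal-variance (Welch) t test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, used to compare total vaccine efficacy
#' between cattle breeds.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return One-row tibble with `statistic`, `p_value`, `df`, `method`.
#' @examples
#' welch_t(c(90, 89, 51), c(47, 50))
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    rlang::abort("welch_t() requires at least 2 observations per sample")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      rlang::abort("statistic undefined: both samples are constant")
    }
    rlang::abort("statistic undefined: zero variance in both samples")
  }
  fit <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  test_result(unname(fit$statistic), fit$p.value, unname(fit$parameter),
              "welch_t")
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (F with k-1 and N-k degrees of
#' freedom), used for per-timepoint antibody-titer comparisons. With all
#' observations equal the decomposition is degenerate (0/0); that case is
#' reported as `F = 0, p = 1` (no evidence of any group difference).
#'
#' @param groups Either a list of numeric vectors (one per group, each with
#'   >= 2 observations) or a data frame with columns `value` and `group`.
#' @return One-row tibble with `statistic` (F), `p_value`, `df` (numerator),
#'   `df2` (denominator) and `method`.
#' @examples
#' oneway_anova(list(c(1, 2), c(5, 6)))
#' @export
oneway_anova <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups))) {
      rlang::abort("data frame input needs `value` and `group` columns")
    }
    groups <- split(as.numeric(groups$value), groups$group)
  }
  if (!is.list(groups) || length(groups) < 2) {
    rlang::abort("oneway_anova() requires at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    rlang::abort("every group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  k <- length(groups); n <- length(values)
  df1 <- k - 1; df2 <- n - k
  if (stats::var(values) == 0) {
    return(test_result(0, 1, df1, "oneway_anova", df2 = df2))
  }
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  stat <- unname(fit$statistic)
  p <- fit$p.value
  if (!is.finite(stat)) { # zero within-group variance, groups differ
    stat <- Inf; p <- 0
  }
  test_result(stat, p, df1, "oneway_anova", df2 = df2)
}

#' Spearman's rank correlation
#'
#' Tie-corrected Spearman's rho, computed as the Pearson correlation of
#' mid-ranks, with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (p = 0 at rho = +/-1, the limit of the approximation).
#'
#' @param x,y Numeric vectors of equal length n >= 3, neither constant.
#' @return One-row tibble with `estimate` (rho), `statistic` (t), `p_value`,
#'   `df` and `method`.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) rlang::abort("x and y must have equal length")
  if (n < 3) rlang::abort("spearman_rho() requires n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("correlation undefined: constant input vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    stat <- sign(rho) * Inf
    p <- 0
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(stat), df = n - 2)
  }
  tibble::tibble(estimate = rho, statistic = stat, p_value = p, df = n - 2,
                 method = "spearman_rho")
}

# Pooled 2x2 chi-square on (successes, failures) per arm; no continuity
# correction. Returns statistic NA / significant FALSE on a zero margin.
pooled_chisq <- function(succ_v, trials_v, succ_c, trials_c, alpha) {
  tab <- rbind(c(succ_v, trials_v - succ_v),
               c(succ_c, trials_c - succ_c))
  if (any(tab < 0)) {
    rlang::abort("pooled table has negative cells; check success/trial totals")
  }
  if (any(rowSums(tab) == 0)) {
    rlang::abort("test undefined: an arm has zero trials (degenerate margin)")
  }
  if (any(colSums(tab) == 0)) {
    return(test_result(NA_real_, NA_real_, 1,
                       "chi_square_pooled (undefined: zero outcome margin)",
                       significant = FALSE, small_sample = FALSE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(fit$statistic), fit$p.value, unname(fit$parameter),
              "chi_square_pooled",
              significant = fit$p.value < alpha,
              small_sample = any(expected < 1))
}

arm_totals <- function(records, parameter, mass_unit_scale) {
  switch(parameter,
    DL  = list(succ = sum(records$larvae_engorged),
               trials = sum(records$larvae_applied)),
    DN  = list(succ = sum(records$nymphs_engorged),
               trials = sum(records$nymphs_applied)),
    DA  = list(succ = sum(records$females_engorged),
               trials = sum(records$females_applied)),
    DMn = list(succ = sum(records$larvae_molted),
               trials = sum(records$larvae_engorged)),
    DMa = list(succ = sum(records$nymphs_molted),
               trials = sum(records$nymphs_engorged)),
    # oviposition: egg-mass units out of one unit-budget (1 g) per engorged
    # female -- valid while per-female egg mass stays below 1 g
    DO  = list(succ = round(sum(records$egg_mass_g) * mass_unit_scale),
               trials = sum(records$females_engorged) * mass_unit_scale),
    # fertility: larval-mass units out of egg-mass units
    DF  = list(succ = round(sum(records$larval_mass_per_g_eggs_g *
                                  records$egg_mass_g) * mass_unit_scale),
               trials = round(sum(records$egg_mass_g) * mass_unit_scale)),
    rlang::abort(paste0("unknown stage parameter: ", parameter))
  )
}

#' Significance gate for one stage parameter
#'
#' Tests whether a stage parameter differs between the vaccinated and control
#' arms, producing the per-parameter significance flag that gates entry into
#' the efficacy product. Under `chi_square_pooled` the animals of each arm are
#' pooled into a single 2x2 arm-by-outcome contingency table (engorged vs not
#' out of applied; molted vs not out of engorged; scaled mass units for the
#' continuous oviposition and fertility parameters) and tested with Pearson's
#' chi-square without continuity correction. Under `rank_per_animal` the
#' per-animal values are compared with an exact Mann-Whitney test.
#'
#' @param vaccinated,control Per-animal record tibbles for the two arms
#'   (columns as in [read_stage_records()]), one row per animal.
#' @param parameter Stage parameter code (`"DL"`, `"DMn"`, ...).
#' @param config A [gate_config()].
#' @return One-row tibble: `statistic`, `p_value`, `df`, `method`,
#'   `significant`, `small_sample` (expected-cell-below-1 caveat; `NA` for the
#'   rank method).
#' @export
chi_square_gate <- function(vaccinated, control, parameter,
                            config = gate_config()) {
  stopifnot(inherits(config, "tickvax_gate_config"))
  if (nrow(vaccinated) < 1 || nrow(control) < 1) {
    rlang::abort("each arm needs at least one animal record")
  }
  if (config$gate_method == "rank_per_animal") {
    vals_v <- animal_parameter_values(vaccinated, parameter)
    vals_c <- animal_parameter_values(control, parameter)
    vals_v <- vals_v[!is.na(vals_v)]; vals_c <- vals_c[!is.na(vals_c)]
    if (length(vals_v) < 1 || length(vals_c) < 1) {
      rlang::abort("test undefined: no usable per-animal values in an arm")
    }
    fit <- suppressWarnings(stats::wilcox.test(vals_v, vals_c, exact = TRUE))
    return(test_result(unname(fit$statistic), fit$p.value, NA_real_,
                       "rank_per_animal",
                       significant = fit$p.value < config$alpha,
                       small_sample = NA))
  }
  tv <- arm_totals(vaccinated, parameter, config$mass_unit_scale)
  tc <- arm_totals(control, parameter, config$mass_unit_scale)
  pooled_chisq(tv$succ, tv$trials, tc$succ, tc$trials, config$alpha)
}
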