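make_serology <- function(vacc_od, ctrl_od, day = 60) {
  tibble::tibble(
    animal_id = c(paste0("v", seq_along(vacc_od)),
                  paste0("c", seq_along(ctrl_od))),
    breed = "crossbred",
    antigen_group = rep(c("vaccine", "control"),
                        c(length(vacc_od), length(ctrl_od))),
    coated_antigen = "Rappendiculatus_SUB",
    day = day, od450 = c(vacc_od, ctrl_od))
}

test_that("timecourse ANOVA flags strong titer separation at the stricter
           level", {
  sero <- make_serology(c(1.2, 1.3, 1.1, 1.25), c(0.2, 0.25, 0.22, 0.21))
  out <- titer_timecourse_test(sero)
  expect_equal(out$signif_label, "**")
  ora <- oracle_anova(list(c(1.2, 1.3, 1.1, 1.25),
                           c(0.2, 0.25, 0.22, 0.21)))
  expect_equal(out$statistic, ora$statistic, tolerance = 1e-9)
  expect_lt(out$p_value, 0.005)
})

test_that("identical titer distributions are not significant", {
  sero <- make_serology(c(0.5, 0.6, 0.7, 0.8), c(0.5, 0.6, 0.7, 0.8))
  out <- titer_timecourse_test(sero)
  expect_equal(out$statistic, 0)
  expect_equal(out$signif_label, "")
})

test_that("a missing control group is an error", {
  sero <- make_serology(c(1, 1.1), c(0.2, 0.3))
  sero <- sero[sero$antigen_group != "control", ]
  expect_error(titer_timecourse_test(sero), "missing control")
})

test_that("titer-stage correlation detects a monotone protective link", {
  titers <- tibble::tibble(animal_id = paste0("a", 1:20),
                           od450 = seq(0.2, 1.5, length.out = 20))
  stage_values <- tibble::tibble(animal_id = paste0("a", 1:20),
                                 parameter = "DL", value = 150:131)
  out <- correlate_titers_stages(titers, stage_values)
  expect_equal(out$rho, -1)
  expect_true(out$significant_negative)
})

test_that("rank-based correlation is invariant to monotone titer
           transforms", {
  set.seed(21)
  titers <- tibble::tibble(animal_id = paste0("a", 1:20),
                           od450 = stats::runif(20, 0.1, 1.5))
  stage_values <- tibble::tibble(animal_id = paste0("a", 1:20),
                                 parameter = "DL",
                                 value = stats::rpois(20, 100))
  base <- correlate_titers_stages(titers, stage_values)
  warped <- correlate_titers_stages(
    dplyr::mutate(titers, od450 = exp(3 * od450)), stage_values)
  expect_equal(base$rho, warped$rho)
  expect_equal(base$p_value, warped$p_value)
})

test_that("unexpected pooled n warns and constant titers abort", {
  titers <- tibble::tibble(animal_id = paste0("a", 1:10), od450 = 1:10 / 10)
  stage_values <- tibble::tibble(animal_id = paste0("a", 1:10),
                                 parameter = "DL", value = 10:1)
  expect_warning(correlate_titers_stages(titers, stage_values),
                 "expected 20")
  const <- dplyr::mutate(titers, od450 = 0.5)
  expect_error(
    suppressWarnings(correlate_titers_stages(const, stage_values)),
    "constant titers")
})

test_that("independent titers rarely produce a significant negative
           correlation", {
  set.seed(22)
  hits <- 0L
  for (i in 1:200) {
    titers <- tibble::tibble(animal_id = paste0("a", 1:20),
                             od450 = stats::rnorm(20, 1, 0.3))
    stage_values <- tibble::tibble(animal_id = paste0("a", 1:20),
                                   parameter = "DL",
                                   value = stats::rpois(20, 100))
    out <- correlate_titers_stages(titers, stage_values)
    hits <- hits + out$significant_negative
  }
  expect_lte(hits / 200, 0.10)
})

test_that("mean reductions joined from a gated table average included rows
           only", {
  titers <- tibble::tibble(animal_id = paste0("a", 1:20),
                           od450 = seq(0.2, 1.5, length.out = 20))
  stage_values <- tibble::tibble(animal_id = paste0("a", 1:20),
                                 parameter = "DL", value = 150:131)
  reds <- tibble::tibble(parameter = "DL", reduction_pct = c(40, 60, 10),
                         included = c(TRUE, TRUE, FALSE))
  out <- correlate_titers_stages(titers, stage_values, reductions = reds)
  expect_equal(out$mean_reduction_pct, mean(c(40, 60, 0)))
})

test_that("the reduction threshold is the smallest significant mean
           reduction", {
  out <- reduction_threshold(tibble::tibble(
    mean_reduction_pct = c(55, 62, 30, 20),
    significant_negative = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(out$threshold_pct, 55)
  expect_true(out$separating)
  all_sig <- reduction_threshold(tibble::tibble(
    mean_reduction_pct = c(41, 70, 55), significant_negative = TRUE))
  expect_equal(all_sig$threshold_pct, 41)
  expect_true(all_sig$separating)
  none <- reduction_threshold(tibble::tibble(
    mean_reduction_pct = c(10, 20), significant_negative = FALSE))
  expect_true(is.na(none$threshold_pct))
  mixed <- reduction_threshold(tibble::tibble(
    mean_reduction_pct = c(55, 60, 20), # a non-significant one sits above
    significant_negative = c(TRUE, FALSE, FALSE)))
  expect_equal(mixed$threshold_pct, 55)
  expect_false(mixed$separating)
})

test_that("removing a non-significant outcome never lowers the threshold", {
  set.seed(23)
  for (i in 1:30) {
    outcomes <- tibble::tibble(
      mean_reduction_pct = stats::runif(6, 0, 100),
      significant_negative = sample(c(TRUE, FALSE), 6, replace = TRUE))
    if (!any(outcomes$significant_negative)) next
    full <- reduction_threshold(outcomes)$threshold_pct
    drop <- which(!outcomes$significant_negative)
    if (length(drop) == 0) next
    reduced <- reduction_threshold(
      outcomes[-sample(drop, 1), ])$threshold_pct
    expect_gte(reduced, full)
  }
})

test_that("eligibility requires significance under at least three
           formulations", {
  elig <- eligible_parameters(reference_reductions())
  pick <- function(b, s) sort(elig$parameter[elig$breed == b &
                                             elig$tick_species == s])
  expect_equal(pick("crossbred", "Rappendiculatus"),
               c("DL", "DMa", "DMn"))
  expect_equal(pick("B_indicus", "Rappendiculatus"), c("DA", "DL", "DMn"))
  expect_equal(pick("crossbred", "Rdecoloratus"), "DF")
})
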