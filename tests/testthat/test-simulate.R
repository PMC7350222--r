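test_that("the same configuration and seed reproduce the trial exactly", {
  cfg <- trial_config()
  a <- simulate_trial(cfg, seed = 5)
  b <- simulate_trial(cfg, seed = 5)
  expect_identical(a$stage_records, b$stage_records)
  expect_identical(a$serology, b$serology)
})

test_that("changing the seed changes the data; changing dose metadata does
           not", {
  cfg <- trial_config()
  a <- simulate_trial(cfg, seed = 5)
  c <- simulate_trial(cfg, seed = 6)
  expect_false(identical(a$stage_records, c$stage_records))
  cfg2 <- trial_config(dose = list(days = c(0, 30, 60), dose_ug = 250,
                                   volume_ml = 5))
  d <- simulate_trial(cfg2, seed = 5)
  expect_identical(a$stage_records, d$stage_records)
  expect_identical(a$serology, d$serology)
})

test_that("simulated records respect the life-stage chain everywhere", {
  trial <- simulate_trial(trial_config(), seed = 9)
  r <- trial$stage_records
  three_host <- r[!is.na(r$larvae_applied), ]
  expect_true(all(three_host$larvae_engorged <= three_host$larvae_applied))
  expect_true(all(three_host$larvae_molted <= three_host$larvae_engorged))
  expect_true(all(three_host$nymphs_engorged <= three_host$nymphs_applied))
  expect_true(all(three_host$nymphs_molted <= three_host$nymphs_engorged))
  expect_true(all(r$females_engorged <= r$females_applied))
  expect_true(all(r$egg_mass_g >= 0))
  # design shape: one-host challenge only in crossbred cattle
  expect_setequal(
    unique(r$breed[r$tick_species == "Rdecoloratus"]), "crossbred")
  expect_equal(nrow(r), 100) # 20 animals x 2 species + 20 x 3 species
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(trial_config(effect_sizes = tibble::tibble(
    antigen_group = "a", tick_species = "s", parameter = "DL",
    effect = 1.5)), "effect sizes")
  expect_error(trial_config(dispersion = -0.1), "dispersion")
  expect_error(trial_config(baseline = list(larval_engorgement = 1.2)),
               "probabilities")
  expect_error(trial_config(baseline = list(egg_mass_per_female_g = 0)),
               "masses must be positive")
})

test_that("with no effect the estimated reductions are centred on zero", {
  set.seed(101)
  cfg <- small_config(effect = 0)
  reds <- vapply(1:200, function(i) {
    trial <- simulate_trial(cfg, seed = NULL)
    s <- summarise_stage_groups(trial$stage_records)
    out <- stage_reduction(s)
    out$reduction_pct[out$parameter == "DL"]
  }, 0)
  expect_lt(abs(mean(reds)), 2)
})

test_that("a configured effect is recovered at low noise and large counts", {
  set.seed(102)
  cfg <- small_config(effect = 0.5, dispersion = 0,
                      challenge = list(larvae_applied = 20000))
  trial <- simulate_trial(cfg, seed = NULL)
  s <- stage_reduction(summarise_stage_groups(trial$stage_records))
  expect_equal(s$reduction_pct[s$parameter == "DL"], 50, tolerance = 0.06)
})

test_that("antibody series are flat at baseline without noise or effect", {
  cfg <- trial_config(titer = list(noise_sd = 0, animal_sd = 0,
                                   dose_increments = c(0, 0, 0)))
  set.seed(1)
  ctrl <- simulate_antibody_series(cfg, "control", "Rappendiculatus_SUB")
  vacc <- simulate_antibody_series(cfg, "Rappendiculatus_SUB",
                                   "Rappendiculatus_SUB")
  expect_equal(ctrl$od450, rep(0.2, 5))
  expect_equal(vacc$od450, rep(0.2, 5))
})

test_that("under the default titer model vaccinated day-60 means exceed
           controls in every replicate", {
  set.seed(103)
  cfg <- trial_config()
  wins <- vapply(1:50, function(i) {
    vacc <- purrr::map_dfr(1:4, function(j) simulate_antibody_series(
      cfg, "Rappendiculatus_SUB", "Rappendiculatus_SUB",
      animal_id = paste0("v", j)))
    ctrl <- purrr::map_dfr(1:4, function(j) simulate_antibody_series(
      cfg, "control", "Rappendiculatus_SUB", animal_id = paste0("c", j)))
    mean(vacc$od450[vacc$day == 60]) > mean(ctrl$od450[ctrl$day == 60])
  }, TRUE)
  expect_true(all(wins))
})

test_that("the third-dose decline mode lowers the end-of-trial response", {
  base <- trial_config(titer = list(noise_sd = 0, animal_sd = 0))
  decl <- trial_config(titer = list(noise_sd = 0, animal_sd = 0,
                                    third_dose_decline = TRUE))
  a <- simulate_antibody_series(base, "Rappendiculatus_SUB",
                                "Rappendiculatus_SUB")
  b <- simulate_antibody_series(decl, "Rappendiculatus_SUB",
                                "Rappendiculatus_SUB")
  expect_lt(b$od450[b$day > 60], a$od450[a$day > 60])
  # the decline only acts after the third dose: earlier bleeds agree
  expect_equal(b$od450[b$day <= 60], a$od450[a$day <= 60])
})

test_that("titer-linked protection raises correlation power with effect
           size", {
  set.seed(104)
  power_at <- function(effect, reps = 100) {
    cfg <- trial_config(
      breeds = "crossbred", antigens = "vaccine",
      three_host_species = "Rappendiculatus",
      one_host_species = character(0), one_host_breeds = character(0),
      animals_per_group = 10,
      effect_sizes = tibble::tibble(
        antigen_group = "vaccine", tick_species = "Rappendiculatus",
        parameter = "DL", effect = effect),
      titer = list(link_strength = 0.8))
    hits <- 0L
    for (i in seq_len(reps)) {
      trial <- simulate_trial(cfg, seed = NULL)
      values <- animal_stage_values(trial$stage_records)
      values <- values[values$parameter == "DL",
                       c("animal_id", "parameter", "value")]
      titers <- trial$serology[trial$serology$day == 60,
                               c("animal_id", "od450")]
      out <- suppressWarnings(correlate_titers_stages(titers, values))
      hits <- hits + out$significant_negative
    }
    hits / reps
  }
  p_small <- power_at(0.15)
  p_large <- power_at(0.6)
  expect_gt(p_large, p_small)
})
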