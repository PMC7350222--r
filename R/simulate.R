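# beta-binomial draws with intraclass correlation rho; rho = 0 is binomial
rbetabinom <- function(n, size, prob, rho) {
  prob <- pmin(pmax(prob, 0), 1)
  out <- integer(n)
  pos <- size > 0 & prob > 0
  if (!any(pos)) return(out)
  if (rho <= 0) {
    out[pos] <- stats::rbinom(sum(pos), size[pos], prob[pos])
    return(out)
  }
  shape <- (1 - rho) / rho
  p <- stats::rbeta(sum(pos), prob[pos] * shape, (1 - prob[pos]) * shape)
  out[pos] <- stats::rbinom(sum(pos), size[pos], p)
  out
}

# log-normal draws parameterised by arithmetic mean and coefficient of
# variation; cv = 0 collapses to the mean
rlnorm_mean <- function(n, mean, cv) {
  if (any(mean < 0)) rlang::abort("log-normal mean must be non-negative")
  if (cv <= 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  out <- stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  out[mean == 0] <- 0
  out
}

#' Trial design and simulation configuration
#'
#' Encodes the full two-breed, five-arm trial design used throughout the
#' package: 2 cattle breeds x 5 vaccine groups (three single subolesin
#' antigens, the combined formulation, and an adjuvant-only control) x 4
#' animals, with a three-host challenge (about 300 larvae, 200 nymphs per
#' ear, 30 adults at a 1 male : 3 female ratio) for R. appendiculatus and
#' A. variegatum, and a one-host challenge (about 300 larvae, all stages on
#' the host) for R. decoloratus in crossbred cattle only. Vaccination days
#' 0/30/60; bleeds on days 0, 30, 45, 60 and at the trial end (day 180 for
#' B. indicus, 195 for crossbred).
#'
#' @param breeds,antigens,control_group Group structure labels.
#' @param animals_per_group Animals per (breed, group) arm.
#' @param three_host_species,one_host_species Tick species by host cycle.
#' @param one_host_breeds Breeds receiving the one-host challenge.
#' @param challenge Named list: `larvae_applied`, `nymphs_per_ear`,
#'   `nymphs_per_animal` (if `TRUE`, analysis totals use both ears, i.e.
#'   2 x `nymphs_per_ear`), `adults_applied`, `females_fraction` (females
#'   among applied adults; 3/4 for the 1:3 male:female ratio),
#'   `one_host_larvae_applied`.
#' @param baseline Control-arm success probabilities and mass means:
#'   `larval_engorgement`, `larval_molting`, `nymphal_engorgement`,
#'   `nymphal_molting`, `female_engorgement`, `one_host_female_yield`
#'   (applied larva to engorged female, whole on-host chain),
#'   `egg_mass_per_female_g`, `larval_mass_per_g_eggs`.
#' @param effect_sizes Tibble of per-(antigen, tick species, parameter)
#'   multiplicative reductions in `[0, 1]` with columns `antigen_group`,
#'   `tick_species`, `parameter`, `effect` and optionally `breed`; missing
#'   combinations mean no effect. Defaults to the reference trial outcomes
#'   ([reference_reductions()]: starred reductions / 100).
#' @param dispersion Beta-binomial intraclass correlation for stage counts
#'   (0 = plain binomial).
#' @param mass_cv Coefficient of variation of the log-normal mass draws.
#' @param titer Antibody model: `baseline_od`, `dose_increments` (OD rise
#'   after each of the three doses), `third_dose_decline` (if `TRUE` the
#'   third increment is a decline, a documented mode of real responses),
#'   `end_retention` (fraction of the cumulative rise retained at trial
#'   end), `noise_sd` (per-reading), `animal_sd` (per-animal frailty),
#'   `cross_reactivity` (response factor against a coated antigen not in the
#'   formulation), `link_strength` (titer-to-protection coupling; 0 = off).
#' @param schedule_days Bleed days shared by both breeds (the end bleed is
#'   appended per breed from `end_day`).
#' @param end_day Named vector of trial-end bleed days per breed.
#' @param dose Dose metadata (days, micrograms, volume); recorded in the
#'   manifest but never used in data generation.
#' @param include_serology Simulate OD450 series (disable for count-only
#'   calibration runs).
#' @param alpha Significance level carried into downstream gating.
#' @param seed Default seed used by [simulate_trial()].
#' @return A list of class `tickvax_trial_config`.
#' @export
trial_config <- function(
    breeds = c("B_indicus", "crossbred"),
    antigens = c("Rappendiculatus_SUB", "Avariegatum_SUB",
                 "Rdecoloratus_SUB", "combined_SUB"),
    control_group = "control",
    animals_per_group = 4,
    three_host_species = c("Rappendiculatus", "Avariegatum"),
    one_host_species = "Rdecoloratus",
    one_host_breeds = "crossbred",
    challenge = list(),
    baseline = list(),
    effect_sizes = NULL,
    dispersion = 0.05,
    mass_cv = 0.2,
    titer = list(),
    schedule_days = c(0, 30, 45, 60),
    end_day = c(B_indicus = 180, crossbred = 195),
    dose = list(days = c(0, 30, 60), dose_ug = 100, volume_ml = 2),
    include_serology = TRUE,
    alpha = 0.05,
    seed = NULL) {
  challenge <- utils::modifyList(list(
    larvae_applied = 300, nymphs_per_ear = 200, nymphs_per_animal = TRUE,
    adults_applied = 30, females_fraction = 3 / 4,
    one_host_larvae_applied = 300), challenge)
  baseline <- utils::modifyList(list(
    larval_engorgement = 0.5, larval_molting = 0.8,
    nymphal_engorgement = 0.5, nymphal_molting = 0.8,
    female_engorgement = 0.7, one_host_female_yield = 0.15,
    egg_mass_per_female_g = 0.25, larval_mass_per_g_eggs = 0.5), baseline)
  titer <- utils::modifyList(list(
    baseline_od = 0.2, dose_increments = c(0.4, 0.5, 0.2),
    third_dose_decline = FALSE, end_retention = 0.6, noise_sd = 0.08,
    animal_sd = 0.15, cross_reactivity = 0.85, link_strength = 0), titer)
  if (is.null(effect_sizes)) {
    ref <- reference_reductions()
    effect_sizes <- tibble::tibble(
      antigen_group = ref$antigen_group, breed = ref$breed,
      tick_species = ref$tick_species, parameter = ref$parameter,
      effect = ifelse(ref$included, ref$reduction_pct / 100, 0))
  }
  effect_sizes <- tibble::as_tibble(effect_sizes)
  probs <- unlist(baseline[c("larval_engorgement", "larval_molting",
                             "nymphal_engorgement", "nymphal_molting",
                             "female_engorgement", "one_host_female_yield")])
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("baseline success probabilities must be in [0, 1]")
  }
  if (baseline$egg_mass_per_female_g <= 0 ||
      baseline$larval_mass_per_g_eggs <= 0) {
    rlang::abort("baseline masses must be positive")
  }
  if (any(effect_sizes$effect < 0 | effect_sizes$effect > 1)) {
    rlang::abort("effect sizes must lie in [0, 1]")
  }
  if (dispersion < 0 || dispersion >= 1) {
    rlang::abort("dispersion must lie in [0, 1)")
  }
  if (animals_per_group < 1) rlang::abort("animals_per_group must be >= 1")
  structure(list(
    breeds = breeds, antigens = antigens, control_group = control_group,
    animals_per_group = animals_per_group,
    three_host_species = three_host_species,
    one_host_species = one_host_species, one_host_breeds = one_host_breeds,
    challenge = challenge, baseline = baseline,
    effect_sizes = effect_sizes, dispersion = dispersion, mass_cv = mass_cv,
    titer = titer, schedule_days = schedule_days, end_day = end_day,
    dose = dose, include_serology = include_serology, alpha = alpha,
    seed = seed), class = "tickvax_trial_config")
}

# effect of (antigen, breed, species, parameter); control and unlisted
# combinations have effect 0
lookup_effect <- function(config, antigen, breed, species, parameter) {
  if (antigen == config$control_group) return(0)
  es <- config$effect_sizes
  hit <- es$antigen_group == antigen & es$tick_species == species &
    es$parameter == parameter
  if ("breed" %in% names(es)) hit <- hit & es$breed == breed
  if (!any(hit)) return(0)
  es$effect[which(hit)[1]]
}

# per-animal realised effect under the optional titer-protection link
animal_effect <- function(effect, u, link_strength) {
  if (link_strength <= 0 || effect <= 0) return(effect)
  pmin(pmax(effect * (1 + link_strength * u), 0), 1)
}

#' Simulate one animal's ELISA OD450 series
#'
#' Control animals fluctuate around the baseline optical density; vaccinated
#' animals rise after each dose (day-30 bleed reflects the first dose, day 45
#' sits mid-way into the second response, day 60 carries the full first two
#' responses) and partially decay by the end bleed. With
#' `titer$third_dose_decline = TRUE` the third-dose increment becomes a
#' decline, a pattern seen in some real responses. Readings are truncated at
#' zero. Draws use the current RNG state; seed externally for
#' reproducibility.
#'
#' @param config A [trial_config()].
#' @param antigen_group Formulation of the animal (control animals keep the
#'   baseline mean).
#' @param coated_antigen Antigen coated on the ELISA plate; heterologous
#'   single-antigen formulations respond at `titer$cross_reactivity`.
#' @param breed Breed label (selects the end-bleed day).
#' @param animal_id Label carried into the output.
#' @param u Per-animal frailty (standard-normal scale) shifting the whole
#'   series by `titer$animal_sd * u` for vaccinated animals.
#' @return Tibble: `animal_id`, `breed`, `antigen_group`, `coated_antigen`,
#'   `day`, `od450`.
#' @export
simulate_antibody_series <- function(config, antigen_group, coated_antigen,
                                     breed = config$breeds[1],
                                     animal_id = "animal_1", u = 0) {
  stopifnot(inherits(config, "tickvax_trial_config"))
  tt <- config$titer
  days <- c(config$schedule_days, unname(config$end_day[breed]))
  if (length(days) == 0) rlang::abort("bleed schedule is empty")
  vaccinated <- antigen_group != config$control_group
  inc <- tt$dose_increments
  if (tt$third_dose_decline) inc[3] <- -abs(inc[3])
  homologous <- antigen_group == "combined_SUB" ||
    antigen_group == coated_antigen
  factor <- if (!vaccinated) 0 else if (homologous) 1 else tt$cross_reactivity
  knots_x <- c(0, 30, 45, 60, max(unname(config$end_day), days))
  knots_y <- tt$baseline_od + factor * c(
    0, inc[1], inc[1] + 0.7 * inc[2], inc[1] + inc[2],
    sum(inc) * tt$end_retention)
  mean_od <- stats::approx(knots_x, knots_y, xout = pmin(days, max(knots_x)),
                           rule = 2)$y
  shift <- if (vaccinated) tt$animal_sd * u else 0
  od <- mean_od + shift + stats::rnorm(length(days), 0, tt$noise_sd)
  tibble::tibble(animal_id = animal_id, breed = breed,
                 antigen_group = antigen_group,
                 coated_antigen = coated_antigen,
                 day = days, od450 = pmax(od, 0))
}

simulate_animal_record <- function(config, animal_id, breed, antigen,
                                   species, one_host, u) {
  ch <- config$challenge; bl <- config$baseline
  rho <- config$dispersion; ls <- config$titer$link_strength
  eff <- function(par) animal_effect(
    lookup_effect(config, antigen, breed, species, par), u, ls)
  if (one_host) {
    fa <- ch$one_host_larvae_applied
    fe <- rbetabinom(1, fa, bl$one_host_female_yield * (1 - eff("DA")), rho)
    la <- le <- lm <- na <- ne <- nm <- NA_integer_
  } else {
    la <- ch$larvae_applied
    le <- rbetabinom(1, la, bl$larval_engorgement * (1 - eff("DL")), rho)
    lm <- rbetabinom(1, le, bl$larval_molting * (1 - eff("DMn")), rho)
    na <- ch$nymphs_per_ear * (1 + ch$nymphs_per_animal)
    ne <- rbetabinom(1, na, bl$nymphal_engorgement * (1 - eff("DN")), rho)
    nm <- rbetabinom(1, ne, bl$nymphal_molting * (1 - eff("DMa")), rho)
    fa <- floor(ch$adults_applied * ch$females_fraction)
    fe <- rbetabinom(1, fa, bl$female_engorgement * (1 - eff("DA")), rho)
  }
  egg_per_female <- rlnorm_mean(
    1, bl$egg_mass_per_female_g * (1 - eff("DO")), config$mass_cv)
  egg_mass <- if (fe > 0) fe * egg_per_female else 0
  larval_mass <- if (egg_mass > 0) {
    rlnorm_mean(1, bl$larval_mass_per_g_eggs * (1 - eff("DF")),
                config$mass_cv)
  } else NA_real_
  tibble::tibble(
    animal_id = animal_id, breed = breed, antigen_group = antigen,
    tick_species = species,
    larvae_applied = la, larvae_engorged = le, larvae_molted = lm,
    nymphs_applied = na, nymphs_engorged = ne, nymphs_molted = nm,
    females_applied = as.integer(fa), females_engorged = as.integer(fe),
    egg_mass_g = egg_mass, larval_mass_per_g_eggs_g = larval_mass)
}

#' Simulate a complete vaccination trial
#'
#' Generates per-animal tick life-stage outcomes and (optionally) OD450
#' antibody series under the configured design. Stage counts follow
#' beta-binomial chains whose vaccinated success probabilities are scaled by
#' `1 - effect`; egg and larval masses are log-normal with vaccinated means
#' scaled the same way. One-host challenges are only applied to the breeds in
#' `config$one_host_breeds`. Output is a pure function of `(config, seed)`.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (defaults to `config$seed`); `NULL` uses the
#'   current RNG state.
#' @return A list of class `tickvax_trial`: `stage_records` (one row per
#'   animal x species), `serology` (one row per animal x coated antigen x
#'   bleed day, or `NULL`), `config`, `seed`.
#' @examples
#' trial <- simulate_trial(trial_config(), seed = 1)
#' dplyr::count(trial$stage_records, breed, tick_species)
#' @export
simulate_trial <- function(config = trial_config(), seed = config$seed) {
  stopifnot(inherits(config, "tickvax_trial_config"))
  if (!is.null(seed)) set.seed(seed)
  groups <- c(config$antigens, config$control_group)
  roster <- tidyr::crossing(
    breed = config$breeds, antigen_group = groups,
    animal = seq_len(config$animals_per_group)) |>
    dplyr::arrange(.data$breed, .data$antigen_group, .data$animal) |>
    dplyr::mutate(animal_id = paste(.data$breed, .data$antigen_group,
                                    .data$animal, sep = "_"),
                  u = stats::rnorm(dplyr::n()))
  records <- purrr::pmap_dfr(roster, function(breed, antigen_group, animal,
                                              animal_id, u) {
    species <- c(config$three_host_species,
                 if (breed %in% config$one_host_breeds)
                   config$one_host_species)
    purrr::map_dfr(species, function(sp) {
      simulate_animal_record(config, animal_id, breed, antigen_group, sp,
                             one_host = sp %in% config$one_host_species, u)
    })
  })
  serology <- NULL
  if (config$include_serology) {
    coated <- setdiff(config$antigens, "combined_SUB")
    if (length(coated) == 0) coated <- config$antigens
    serology <- purrr::pmap_dfr(roster, function(breed, antigen_group,
                                                 animal, animal_id, u) {
      purrr::map_dfr(coated, function(ca) {
        simulate_antibody_series(config, antigen_group, ca, breed,
                                 animal_id, u)
      })
    })
  }
  structure(list(stage_records = records, serology = serology,
                 config = config, seed = seed),
            class = "tickvax_trial")
}

#' @export
print.tickvax_trial <- function(x, ...) {
  cat("<tickvax_trial>\n")
  cat("  stage records:", nrow(x$stage_records), "animal x species rows\n")
  if (!is.null(x$serology)) {
    cat("  serology:     ", nrow(x$serology), "OD450 readings\n")
  }
  cat("  seed:         ", if (is.null(x$seed)) "<none>" else x$seed, "\n")
  invisible(x)
}
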