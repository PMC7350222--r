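# Independent textbook-formula oracles used to cross-check the package's
# statistical routines. These never call the functions they validate.

oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

oracle_anova <- function(groups) {
  values <- unlist(groups)
  gm <- mean(values)
  k <- length(groups); n <- length(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# brute-force mid-ranks: position-count definition, no call to rank()
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# minimal per-animal record builder for gate tests; scalar arguments are
# recycled across the n animals of the arm
make_arm <- function(n = 4, antigen = "vaccine", breed = "crossbred",
                     species = "Rappendiculatus",
                     larvae_applied = 300, larvae_engorged = 150,
                     larvae_molted = 120,
                     nymphs_applied = 400, nymphs_engorged = 200,
                     nymphs_molted = 160,
                     females_applied = 22, females_engorged = 15,
                     egg_mass_g = 3, larval_mass_per_g_eggs_g = 0.5) {
  tibble::tibble(
    animal_id = paste0(antigen, "_", seq_len(n)),
    breed = breed, antigen_group = antigen, tick_species = species,
    larvae_applied = larvae_applied, larvae_engorged = larvae_engorged,
    larvae_molted = larvae_molted,
    nymphs_applied = nymphs_applied, nymphs_engorged = nymphs_engorged,
    nymphs_molted = nymphs_molted,
    females_applied = females_applied, females_engorged = females_engorged,
    egg_mass_g = egg_mass_g,
    larval_mass_per_g_eggs_g = larval_mass_per_g_eggs_g)
}

# small single-species design used by simulation-heavy tests: one vaccinated
# arm and its control, three-host chain only, no serology
small_config <- function(effect = 0, parameter = "DL", dispersion = 0.05,
                         ...) {
  trial_config(
    breeds = "crossbred", antigens = "vaccine", control_group = "control",
    three_host_species = "Rappendiculatus",
    one_host_species = character(0), one_host_breeds = character(0),
    effect_sizes = tibble::tibble(
      antigen_group = "vaccine", tick_species = "Rappendiculatus",
      parameter = parameter, effect = effect),
    dispersion = dispersion, include_serology = FALSE, ...)
}
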