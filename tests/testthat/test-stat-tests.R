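test_that("welch_t matches the direct Welch-Satterthwaite formulas", {
  out <- welch_t(c(90, 89, 51), c(47, 50))
  ora <- oracle_welch(c(90, 89, 51), c(47, 50))
  expect_equal(out$statistic, ora$statistic, tolerance = 1e-9)
  expect_equal(out$df, ora$df, tolerance = 1e-9)
  expect_equal(out$p_value, ora$p_value, tolerance = 1e-9)
})

test_that("welch_t handles identical and degenerate samples", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(0, 0), c(0, 0)), "undefined")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("welch_t is antisymmetric under sample exchange", {
  set.seed(11)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:8, 1)); b <- stats::rnorm(sample(2:8, 1))
    ab <- welch_t(a, b); ba <- welch_t(b, a)
    expect_equal(ab$statistic, -ba$statistic)
    expect_equal(ab$p_value, ba$p_value)
  }
})

test_that("oneway_anova matches the sums-of-squares decomposition", {
  out <- oneway_anova(list(c(1, 2), c(5, 6)))
  ora <- oracle_anova(list(c(1, 2), c(5, 6)))
  expect_equal(out$statistic, ora$statistic, tolerance = 1e-9)
  expect_equal(out$p_value, ora$p_value, tolerance = 1e-9)
  expect_equal(out$statistic, 32)
  expect_equal(c(out$df, out$df2), c(1, 2))
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(12)
  for (i in 1:25) {
    a <- stats::rnorm(sample(3:9, 1)); b <- stats::rnorm(sample(3:9, 1))
    f <- oneway_anova(list(a, b))$statistic
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-9)
  }
})

test_that("oneway_anova degenerate inputs behave as documented", {
  flat <- oneway_anova(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(oneway_anova(list(1, c(2, 3))), "at least 2 observations")
  expect_error(oneway_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("oneway_anova is invariant to shifts and positive rescaling", {
  set.seed(13)
  groups <- list(stats::rnorm(4), stats::rnorm(5), stats::rnorm(4))
  f0 <- oneway_anova(groups)$statistic
  expect_equal(oneway_anova(lapply(groups, function(g) g + 7))$statistic, f0,
               tolerance = 1e-9)
  expect_equal(oneway_anova(lapply(groups, function(g) g * 3.5))$statistic,
               f0, tolerance = 1e-9)
})

test_that("spearman_rho is the tie-corrected mid-rank Pearson correlation", {
  out <- spearman_rho(c(1, 2, 2, 4), c(3, 1, 2, 0))
  expect_equal(out$estimate, oracle_spearman(c(1, 2, 2, 4), c(3, 1, 2, 0)),
               tolerance = 1e-12)
  expect_equal(spearman_rho(1:5, c(10, 20, 30, 40, 55))$estimate, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$estimate, -1)
  expect_equal(spearman_rho(1:5, -(1:5))$p_value, 0)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("spearman_rho agrees with the brute-force oracle on all short
           inputs with ties", {
  set.seed(14)
  for (n in 3:6) {
    for (i in 1:150) {
      x <- sample(1:3, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (stats::var(x) == 0 || stats::var(y) == 0) next
      expect_equal(spearman_rho(x, y)$estimate, oracle_spearman(x, y),
                   tolerance = 1e-12)
      expect_equal(spearman_rho(x, y)$estimate,
                   stats::cor(x, y, method = "spearman"),
                   tolerance = 1e-12)
    }
  }
})

test_that("spearman_rho p-values follow the t approximation", {
  set.seed(15)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  out <- spearman_rho(x, y)
  t <- out$estimate * sqrt((10 - 2) / (1 - out$estimate^2))
  expect_equal(out$p_value, 2 * stats::pt(-abs(t), 8), tolerance = 1e-12)
})

test_that("pooled chi-square gate matches the textbook statistic", {
  vacc <- make_arm(n = 1, larvae_engorged = 10, larvae_applied = 300)
  ctrl <- make_arm(n = 1, antigen = "control", larvae_engorged = 100,
                   larvae_applied = 300)
  out <- chi_square_gate(vacc, ctrl, "DL")
  ora <- oracle_chisq_2x2(rbind(c(10, 290), c(100, 200)))
  expect_equal(out$statistic, ora$statistic, tolerance = 1e-9)
  expect_equal(out$p_value, ora$p_value, tolerance = 1e-9)
  expect_true(out$significant)
})

test_that("identical pooled proportions give a null chi-square", {
  vacc <- make_arm(larvae_engorged = 150)
  ctrl <- make_arm(antigen = "control", larvae_engorged = 150)
  out <- chi_square_gate(vacc, ctrl, "DL")
  expect_equal(out$statistic, 0)
  expect_false(out$significant)
})

test_that("degenerate tables are rejected or flagged undefined", {
  vacc <- make_arm(larvae_applied = 0, larvae_engorged = 0,
                   larvae_molted = 0)
  ctrl <- make_arm(antigen = "control")
  expect_error(chi_square_gate(vacc, ctrl, "DL"), "degenerate margin")
  # zero outcome margin: every applied larva engorged in both arms
  vacc2 <- make_arm(larvae_engorged = 300, larvae_molted = 200)
  ctrl2 <- make_arm(antigen = "control", larvae_engorged = 300,
                    larvae_molted = 200)
  out <- chi_square_gate(vacc2, ctrl2, "DL")
  expect_true(is.na(out$statistic))
  expect_false(out$significant)
})

test_that("mass parameters gate through scaled pseudo-counts", {
  vacc <- make_arm(females_engorged = 10, egg_mass_g = 1.5)
  ctrl <- make_arm(antigen = "control", females_engorged = 10,
                   egg_mass_g = 3)
  out <- chi_square_gate(vacc, ctrl, "DO")
  # 4 animals x 1.5 g -> 6000 units of 40000; control 12000 of 40000
  ora <- oracle_chisq_2x2(rbind(c(6000, 34000), c(12000, 28000)))
  expect_equal(out$statistic, ora$statistic, tolerance = 1e-9)
  expect_true(out$significant)
})

test_that("the per-animal rank gate applies the exact Mann-Whitney test", {
  vacc <- make_arm(egg_mass_g = c(1.0, 1.1, 1.2, 1.3),
                   females_engorged = 10)
  ctrl <- make_arm(antigen = "control", females_engorged = 10,
                   egg_mass_g = c(2.9, 3.0, 3.1, 3.2))
  out <- chi_square_gate(vacc, ctrl, "DO",
                         gate_config(gate_method = "rank_per_animal"))
  # full separation of 4 vs 4: exact two-sided p = 2/choose(8,4)
  expect_equal(out$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(out$significant)
})

test_that("gate configuration validates its inputs", {
  expect_error(gate_config(alpha = 0), "strictly between")
  expect_error(gate_config(alpha = 1), "strictly between")
  expect_error(gate_config(mass_unit_scale = -1), "positive")
  expect_equal(gate_config()$gate_method, "chi_square_pooled")
})
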