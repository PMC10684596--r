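test_that("degenerate model reproduces the trait means exactly", {
  d <- build_design(6, 2, 2, 3, seed = 1)
  m <- trait_model(c("A", "B"), mu = c(3, -1),
                   sigma_g = matrix(0, 2, 2), sigma_ge = matrix(0, 2, 2),
                   sigma_e = matrix(0, 2, 2))
  tab <- simulate_trial(d, m, seed = 5)
  expect_equal(tab$value[tab$trait == "A"], rep(3, 24))
  expect_equal(tab$value[tab$trait == "B"], rep(-1, 24))
})

test_that("simulated tables are balanced, complete and reproducible", {
  d <- build_design(12, 2, 2, 4, seed = 3)
  m <- trait_model(c("A", "B", "C"), mu = c(0, 0, 0),
                   sigma_g = diag(3), sigma_ge = 0.3 * diag(3),
                   sigma_e = 0.5 * diag(3),
                   season_sd = 0.4, rep_sd = 0.2, block_sd = 0.3)
  t1 <- simulate_trial(d, m, seed = 11)
  expect_equal(nrow(t1), 12 * 2 * 2 * 3)
  expect_true(check_balance(t1))
  t2 <- simulate_trial(d, m, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_trial(d, m, seed = 12)
  expect_false(identical(t1$value, t3$value))
})

test_that("configured genotypic correlation is recovered from genotype means", {
  d <- build_design(500, 2, 2, 20, seed = 2)
  m <- two_trait_model(r_g = 0.8, ge_scale = 0.01, e_scale = 0.01)
  for (seed in c(101, 202, 303)) {
    tab <- simulate_trial(d, m, seed = seed)
    wide <- tapply(tab$value, list(tab$genotype, tab$trait), mean)
    expect_gt(cor(wide[, "A"], wide[, "B"]), 0.75)
    expect_lt(cor(wide[, "A"], wide[, "B"]), 0.85)
  }
})

test_that("empirical genotype-effect variance tracks the sigma_g diagonal", {
  d <- build_design(200, 1, 1, 20, seed = 4)
  m <- trait_model(c("A", "B"), mu = c(5, 9),
                   sigma_g = diag(c(2, 0.5)), sigma_ge = matrix(0, 2, 2),
                   sigma_e = matrix(0, 2, 2))
  vars <- vapply(1:20, function(seed) {
    tab <- simulate_trial(d, m, seed = 500 + seed)
    c(var(tab$value[tab$trait == "A"]), var(tab$value[tab$trait == "B"]))
  }, numeric(2))
  expect_lt(abs(mean(vars[1, ]) - 2) / 2, 0.15)
  expect_lt(abs(mean(vars[2, ]) - 0.5) / 0.5, 0.15)
})

test_that("non-PSD covariance is rejected naming the offending matrix", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3, -1
  expect_error(
    trait_model(c("A", "B"), c(0, 0), sigma_g = bad,
                sigma_ge = diag(2), sigma_e = diag(2)),
    "sigma_g.*positive semi-definite")
  expect_error(
    trait_model(c("A", "B"), c(0, 0), sigma_g = diag(2),
                sigma_ge = bad, sigma_e = diag(2)),
    "sigma_ge")
})

test_that("balance checker flags missing and duplicated cells", {
  d <- build_design(4, 2, 2, 2, seed = 1)
  m <- trait_model("A", 0, matrix(1), matrix(0), matrix(0.1))
  tab <- simulate_trial(d, m, seed = 1)
  expect_true(check_balance(tab))
  expect_error(check_balance(tab[-1, ]), "not balanced")
  expect_error(check_balance(rbind(tab, tab[1, ])), "not balanced")
  tab$value[1] <- NA
  expect_error(check_balance(tab), "non-finite")
})

test_that("grain filling rate and period follow their definitions", {
  expect_equal(derive_gsfr(2.0, 60, 100), 50.0)
  expect_equal(derive_gsfr(0, 60, 100), 0)
  expect_equal(derive_gfp(60, 100), 40)
  expect_error(derive_gsfr(1.5, 100, 100), "positive")
  expect_error(derive_gsfr(-1, 60, 100), "non-negative")
})

test_that("spectral repair yields a PSD unit-diagonal matrix", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # inconsistent
  ev0 <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev0), 0)
  Rfix <- repair_correlation(R)
  ev <- eigen(Rfix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(diag(Rfix), rep(1, 3))
})

test_that("the amaranth fixture has the study's shape and structure", {
  fx <- amaranth_fixture(seed = 42)
  expect_equal(nrow(fx$table), 120 * 2 * 2 * 24)
  expect_true(check_balance(fx$table))
  expect_identical(amaranth_fixture(seed = 42)$table, fx$table)
  # configured genotypic correlation matrix is PSD with the anchor pairs intact
  R <- amaranth_correlations()
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(R["LW", "LL"]), 0.9, tolerance = 1e-8)
  expect_equal(unname(R["GY", "GSFR"]), 0.9, tolerance = 1e-8)
})
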