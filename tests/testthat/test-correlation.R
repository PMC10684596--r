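test_that("significance marks follow the tabulated critical r at n-2 df", {
  # inverse-t oracle at df = 118: critical |r| = t / sqrt(df + t^2)
  crit <- function(alpha) {
    t <- qt(1 - alpha / 2, df = 118)
    t / sqrt(118 + t^2)
  }
  expect_equal(crit(0.05), 0.1793, tolerance = 1e-3)
  expect_equal(crit(0.001), 0.297, tolerance = 2e-3)
  expect_equal(correlation_significance(0, 120), "ns")
  expect_equal(correlation_significance(0.18, 120), "*")
  expect_equal(correlation_significance(0.30, 120), "***")
  expect_equal(correlation_significance(-0.30, 120), "***")
  expect_equal(correlation_significance(1.05, 120), "***")
  expect_error(correlation_significance(0.5, 2), "n >= 3")
})

test_that("significance is monotone in |r| for fixed n", {
  marks <- c(ns = 0, `*` = 1, `**` = 2, `***` = 3)
  for (n in c(10, 50, 120)) {
    grades <- marks[correlation_significance(seq(0, 1, by = 0.005), n)]
    expect_true(all(diff(grades) >= 0))
  }
})

test_that("correlations of a trait with itself and its scalings are one", {
  tab <- random_table(G = 8, seasons = 2, reps = 2, traits = "A", seed = 3)
  doubled <- tab[tab$trait == "A", ]
  doubled$trait <- "B"
  doubled$value <- 2 * doubled$value + 5
  tab <- rbind(tab, doubled)
  msA <- mean_squares(tab, "A"); msB <- mean_squares(tab, "B")
  comp <- estimate_components(msA, msB, mean_cross_products(tab, "A", "B"))
  expect_equal(phenotypic_correlation(comp)$r, 1, tolerance = 1e-10)
  expect_equal(genotypic_correlation(comp)$r, 1, tolerance = 1e-10)
})

test_that("zero covariance gives zero correlation with an ns mark", {
  tab <- make_table(matrix(c(-1, 0, 1, 2, -2, 0), 3,
                           dimnames = list(NULL, c("A", "B"))),
                    e_eff = function(g, s, r) c(0, 0))
  # orthogonalize trait B against A at the genotype level: cov of effects
  # (-1,0,1).(2,-2,0) = -2 ... construct exact zero instead
  gB <- c(1, -2, 1)   # orthogonal to (-1, 0, 1)
  tab <- make_table(cbind(A = c(-1, 0, 1), B = gB))
  comp <- estimate_components(mean_squares(tab, "A"), mean_squares(tab, "B"),
                              mean_cross_products(tab, "A", "B"))
  expect_equal(phenotypic_correlation(comp)$r, 0, tolerance = 1e-12)
  expect_equal(phenotypic_correlation(comp)$significance, "ns")
  expect_equal(genotypic_correlation(comp)$r, 0, tolerance = 1e-12)
})

test_that("clipped genotypic variance propagates as an undefined correlation", {
  # no genotype main effect, strong crossover GxE: sigma2_g clips to zero
  ge <- list(matrix(c(1, -1, 1, -1), 4, 2), matrix(c(-1, 1, -1, 1), 4, 2))
  tab <- make_table(matrix(0, 4, 2, dimnames = list(NULL, c("A", "B"))),
                    ge_eff = lapply(ge, function(m) {
                      colnames(m) <- c("A", "B"); m
                    }))
  comp <- estimate_components(mean_squares(tab, "A"), mean_squares(tab, "B"),
                              mean_cross_products(tab, "A", "B"))
  expect_equal(unname(comp$var_g), c(0, 0))
  est <- genotypic_correlation(comp)
  expect_true(is.na(est$r))
  expect_match(est$reason, "clipped")
})

test_that("zero phenotypic variance is an explicit error", {
  tab <- make_table(matrix(0, 3, 2, dimnames = list(NULL, c("A", "B"))))
  comp <- estimate_components(mean_squares(tab, "A"), mean_squares(tab, "B"),
                              mean_cross_products(tab, "A", "B"))
  expect_error(phenotypic_correlation(comp), "phenotypic variance is zero")
})

test_that("mean-basis phenotypic correlation equals the genotype-mean correlation", {
  d <- build_design(60, 2, 2, 10, seed = 5)
  m <- trait_model(c("A", "B"), c(0, 0),
                   sigma_g = matrix(c(1, .5, .5, 1), 2),
                   sigma_ge = 0.3 * diag(2), sigma_e = 0.5 * diag(2))
  tab <- simulate_trial(d, m, seed = 31)
  cm <- correlation_matrices(tab, c("A", "B"))
  means <- tapply(tab$value, list(tab$genotype, tab$trait), mean)
  expect_equal(unname(cm$rp["A", "B"]), cor(means[, "A"], means[, "B"]),
               tolerance = 0.02)
})

test_that("genotypic correlation estimates recover the simulated value", {
  d <- build_design(500, 2, 2, 20, seed = 8)
  m <- two_trait_model(r_g = 0.8)
  for (seed in c(41, 42)) {
    tab <- simulate_trial(d, m, seed = seed)
    cm <- correlation_matrices(tab, c("A", "B"))
    expect_equal(unname(cm$rg["A", "B"]), 0.8, tolerance = 0.05)
  }
})

test_that("correlation matrices are symmetric with unit diagonal and full significance", {
  tab <- random_table(G = 20, seasons = 2, reps = 2,
                      traits = c("A", "B", "C", "D"), seed = 10)
  cm <- correlation_matrices(tab, c("A", "B", "C", "D"))
  expect_equal(cm$rp, t(cm$rp))
  expect_equal(cm$rg, t(cm$rg))
  expect_equal(unname(diag(cm$rp)), rep(1, 4))
  expect_true(all(abs(cm$rp) <= 1 + 1e-12))
  expect_true(all(cm$sig_p[upper.tri(cm$sig_p)] %in% c("ns", "*", "**", "***")))
  expect_equal(cm$n, 20)
  # out-of-range genotypic estimates flagged, and clamped on request
  if (any(cm$rg_out_of_range)) {
    clamped <- correlation_matrices(tab, c("A", "B", "C", "D"), clamp = TRUE)
    expect_true(all(abs(clamped$rg) <= 1))
  }
  lines <- format_correlation_table(cm)
  expect_length(lines, 5)
})

test_that("per-pair matrices match the fast all-pairs engine when blocks are absorbed", {
  d <- build_design(10, 2, 2, 5, seed = 13)
  m <- trait_model(c("A", "B"), c(0, 0),
                   sigma_g = matrix(c(1, .6, .6, 1), 2),
                   sigma_ge = 0.2 * diag(2), sigma_e = 0.4 * diag(2))
  tab <- simulate_trial(d, m, seed = 14)
  fast <- correlation_matrices(tab, c("A", "B"))
  slow <- correlation_matrices(tab, c("A", "B"), blocks = "absorb")
  # same data, different block handling: close but not identical
  expect_equal(unname(slow$rp["A", "B"]), unname(fast$rp["A", "B"]),
               tolerance = 0.1)
  expect_equal(slow$n, 10)
})
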