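test_that("genotype mean square matches the hand-derived value", {
  # 3 genotypes x 2 seasons x 2 reps, genotype effects (-1, 0, 1), nothing else:
  # MS_g = r*s*sum(effects^2)/(G-1) = 4*2/2 = 4; all other strata zero
  tab <- make_table(matrix(c(-1, 0, 1), 3, dimnames = list(NULL, "Y")))
  ms <- ms_named(mean_squares(tab, "Y"))
  expect_equal(unname(ms["genotype"]), 4.0)
  expect_equal(unname(ms["genotype_x_environment"]), 0)
  expect_equal(unname(ms["error"]), 0)
})

test_that("constant table gives all-zero mean squares", {
  tab <- make_table(matrix(0, 4, 1, dimnames = list(NULL, "Y")), mu = 7)
  expect_true(all(abs(mean_squares(tab, "Y")$ms) < 1e-12))
})

test_that("missing plots abort the analysis", {
  tab <- make_table(matrix(rnorm(4), 4, 1, dimnames = list(NULL, "Y")))
  expect_error(mean_squares(tab[-1, ], "Y"), "not balanced")
})

test_that("stratum sums agree with the brute-force double-loop oracle", {
  for (seed in 1:3) {
    tab <- random_table(G = 4, seasons = 2, reps = 2,
                        traits = c("A", "B"), seed = seed)
    for (pair in list(c("A", "A"), c("A", "B"), c("B", "B"))) {
      got <- mean_cross_products(tab, pair[1], pair[2])
      oracle <- brute_strata(tab, pair[1], pair[2])
      expect_equal(stats::setNames(got$ms * got$df, got$source), oracle$cp,
                   tolerance = 1e-10)
      expect_equal(stats::setNames(as.numeric(got$df), got$source), oracle$df)
    }
  }
})

test_that("stratum sums agree with sequential aov on balanced data", {
  tab <- random_table(G = 5, seasons = 2, reps = 2, traits = "A", seed = 9)
  got <- mean_squares(tab, "A")
  sub <- tab[tab$trait == "A", ]
  sub$g <- factor(sub$genotype); sub$s <- factor(sub$season); sub$r <- factor(sub$rep)
  a <- anova(lm(value ~ s + s:r + g + s:g, data = sub))
  ss <- stats::setNames(a[["Sum Sq"]], rownames(a))
  cp <- stats::setNames(got$ms * got$df, got$source)
  expect_equal(unname(cp["environment"]), unname(ss["s"]), tolerance = 1e-10)
  expect_equal(unname(cp["rep_within_env"]), unname(ss["s:r"]), tolerance = 1e-10)
  expect_equal(unname(cp["genotype"]), unname(ss["g"]), tolerance = 1e-10)
  expect_equal(unname(cp["genotype_x_environment"]), unname(ss["s:g"]),
               tolerance = 1e-10)
  expect_equal(unname(cp["error"]), unname(ss["Residuals"]), tolerance = 1e-10)
})

test_that("cross-products are bilinear and reduce to mean squares on the diagonal", {
  tab <- random_table(G = 6, seasons = 2, reps = 2, traits = "A", seed = 4)
  doubled <- tab[tab$trait == "A", ]
  doubled$trait <- "B"
  doubled$value <- 2 * doubled$value
  tab2 <- rbind(tab, doubled)
  msA <- mean_squares(tab2, "A")
  self <- mean_cross_products(tab2, "A", "A")
  expect_equal(self$ms, msA$ms, tolerance = 1e-12)
  cross <- mean_cross_products(tab2, "A", "B")
  expect_equal(cross$ms, 2 * msA$ms, tolerance = 1e-10)
})

test_that("genotype-stratum cross-product of independent traits is near zero", {
  set.seed(77)
  G <- 200
  g_eff <- matrix(rnorm(2 * G), G, dimnames = list(NULL, c("A", "B")))
  tab <- make_table(g_eff, e_eff = function(g, s, r) rnorm(2, sd = 0.3))
  mcp <- ms_named(mean_cross_products(tab, "A", "B"))
  # MCP_g/(r*s) estimates cov of genotype means; s.e. ~ 1/sqrt(G-1)
  expect_lt(abs(mcp["genotype"] / 4), 3 / sqrt(G - 1))
})

test_that("the EMS ladder solves the variance components", {
  tab <- make_table(matrix(c(-1, 0, 1), 3, dimnames = list(NULL, "Y")))
  ms <- mean_squares(tab, "Y")
  comp <- estimate_components(ms, ms, ms)
  expect_equal(unname(comp$var_g[1]), 1.0)   # (4 - 0) / (r*s) = 1
  expect_equal(unname(comp$var_ge[1]), 0)
  expect_equal(unname(comp$var_e[1]), 0)
  # self-consistency: covariance components equal variance components
  expect_equal(comp$cov_g, unname(comp$var_g[1]))
  expect_equal(comp$cov_ge, unname(comp$var_ge[1]))
  expect_equal(comp$cov_e, unname(comp$var_e[1]))
  # mean-basis identity
  expect_equal(unname(comp$var_p[1]),
               unname(comp$var_g[1] + comp$var_ge[1] / 2 + comp$var_e[1] / 4))
})

test_that("equal mean squares collapse the ladder onto the error component", {
  fake <- function(ms_g, ms_ge, ms_e) {
    tab <- mean_squares(make_table(matrix(c(-1, 0, 1), 3,
                                          dimnames = list(NULL, "Y"))), "Y")
    tab$ms[match(c("genotype", "genotype_x_environment", "error"), tab$source)] <-
      c(ms_g, ms_ge, ms_e)
    tab
  }
  comp <- estimate_components(fake(3, 3, 3), fake(3, 3, 3), fake(3, 3, 3))
  expect_equal(unname(comp$var_g[1]), 0)
  expect_equal(unname(comp$var_ge[1]), 0)
  expect_equal(unname(comp$var_e[1]), 3)
  expect_false(any(comp$truncated))

  # MS_g < MS_ge: genotype component clips to zero with a flag
  comp2 <- estimate_components(fake(1, 3, 0.5), fake(1, 3, 0.5), fake(1, 3, 0.5))
  expect_equal(unname(comp2$var_g[1]), 0)
  expect_true(comp2$truncated["x", "g"])
  # covariance ladder keeps its sign
  expect_lt(comp2$cov_g, 0)
})

test_that("plot-basis phenotypic variance sums the raw components", {
  tab <- random_table(G = 5, seasons = 2, reps = 2, traits = "A", seed = 12)
  ms <- mean_squares(tab, "A")
  comp <- estimate_components(ms, ms, ms, basis = "plot")
  expect_equal(unname(comp$var_p[1]),
               unname(comp$var_g[1] + comp$var_ge[1] + comp$var_e[1]))
})

test_that("absorbing the block stratum removes block noise from the error", {
  d <- build_design(12, 2, 2, 4, seed = 6)
  m <- trait_model("Y", 0, matrix(1), matrix(0.2), matrix(0.3), block_sd = 3)
  tab <- simulate_trial(d, m, seed = 21)
  plain <- ms_named(mean_squares(tab, "Y"))
  absorbed <- mean_squares(tab, "Y", blocks = "absorb")
  expect_true("block_within_rep" %in% absorbed$source)
  expect_lt(ms_named(absorbed)["error"], plain["error"] / 2)
  # polarization-based cross-products stay consistent with the diagonal
  self <- mean_cross_products(tab, "Y", "Y", blocks = "absorb")
  expect_equal(self$ms, absorbed$ms, tolerance = 1e-10)
})
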