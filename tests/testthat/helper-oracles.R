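# Shared fixtures and independent oracles for the test suite.

# Build a balanced plot table from explicit effect arrays so expected
# ANOVA quantities can be derived by hand.
#   g_eff: G x k matrix of genotype effects
#   ge_eff: list over seasons of G x k matrices
#   e_eff: function(g, s, r) -> k-vector of plot errors (default zero)
make_table <- function(g_eff, seasons = 2, reps = 2, mu = 0,
                       ge_eff = NULL, e_eff = NULL,
                       season_eff = rep(0, seasons),
                       rep_eff = matrix(0, seasons, reps)) {
  G <- nrow(g_eff)
  k <- ncol(g_eff)
  traits <- colnames(g_eff)
  if (is.null(traits)) traits <- paste0("T", seq_len(k))
  rows <- list()
  for (g in seq_len(G)) for (s in seq_len(seasons)) for (r in seq_len(reps)) {
    val <- mu + season_eff[s] + rep_eff[s, r] + g_eff[g, ]
    if (!is.null(ge_eff)) val <- val + ge_eff[[s]][g, ]
    if (!is.null(e_eff)) val <- val + e_eff(g, s, r)
    rows[[length(rows) + 1]] <- data.frame(
      genotype = sprintf("G%02d", g), season = s, rep = r, block = 1,
      trait = traits, value = as.numeric(val), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Brute-force stratum sums of cross-products by explicit double loops over
# the records; deliberately independent of the package's rowsum/crossprod
# engine.
brute_strata <- function(tab, tx, ty) {
  sub_x <- tab[tab$trait == tx, ]
  sub_y <- tab[tab$trait == ty, ]
  key <- function(d) paste(d$genotype, d$season, d$rep)
  sub_y <- sub_y[match(key(sub_x), key(sub_y)), ]
  x <- sub_x$value; y <- sub_y$value
  g <- sub_x$genotype; s <- sub_x$season; r <- sub_x$rep
  G <- length(unique(g)); S <- length(unique(s)); R <- length(unique(r))
  mx <- mean(x); my <- mean(y)
  cp_total <- 0
  for (i in seq_along(x)) cp_total <- cp_total + (x[i] - mx) * (y[i] - my)
  cp_g <- 0
  for (gg in unique(g)) {
    cp_g <- cp_g + S * R * (mean(x[g == gg]) - mx) * (mean(y[g == gg]) - my)
  }
  cp_env <- 0
  for (ss in unique(s)) {
    cp_env <- cp_env + G * R * (mean(x[s == ss]) - mx) * (mean(y[s == ss]) - my)
  }
  cp_rep <- 0
  for (ss in unique(s)) for (rr in unique(r)) {
    sel <- s == ss & r == rr
    cp_rep <- cp_rep + G * (mean(x[sel]) - mean(x[s == ss])) *
      (mean(y[sel]) - mean(y[s == ss]))
  }
  cp_ge <- 0
  for (gg in unique(g)) for (ss in unique(s)) {
    sel <- g == gg & s == ss
    dx <- mean(x[sel]) - mean(x[g == gg]) - mean(x[s == ss]) + mx
    dy <- mean(y[sel]) - mean(y[g == gg]) - mean(y[s == ss]) + my
    cp_ge <- cp_ge + R * dx * dy
  }
  cp_e <- cp_total - cp_g - cp_env - cp_rep - cp_ge
  list(cp = c(environment = cp_env, rep_within_env = cp_rep, genotype = cp_g,
              genotype_x_environment = cp_ge, error = cp_e),
       df = c(environment = S - 1, rep_within_env = S * (R - 1),
              genotype = G - 1, genotype_x_environment = (G - 1) * (S - 1),
              error = S * (G - 1) * (R - 1)))
}

# Random small balanced table for property checks.
random_table <- function(G, seasons, reps, traits, seed) {
  set.seed(seed)
  g_eff <- matrix(rnorm(G * length(traits)), G,
                  dimnames = list(NULL, traits))
  ge <- lapply(seq_len(seasons), function(s)
    matrix(rnorm(G * length(traits), sd = 0.7), G))
  make_table(g_eff, seasons, reps,
             mu = rnorm(1), ge_eff = ge,
             e_eff = function(g, s, r) rnorm(length(traits), sd = 0.5),
             season_eff = rnorm(seasons), rep_eff = matrix(rnorm(seasons * reps), seasons))
}

# Two-trait simulation with configurable genetic correlation, used for the
# recovery checks.
two_trait_model <- function(r_g, ge_scale = 0.05, e_scale = 0.05) {
  sg <- matrix(c(1, r_g, r_g, 1), 2)
  trait_model(c("A", "B"), mu = c(0, 0), sigma_g = sg,
              sigma_ge = ge_scale * diag(2), sigma_e = e_scale * diag(2))
}

ms_named <- function(tab) stats::setNames(tab$ms, tab$source)
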