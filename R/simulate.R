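#' Simulate a balanced multi-environment trial
#'
#' Draws plot-level observations for every trait under the additive random
#' model of [trait_model()]: genotype effects shared across seasons,
#' genotype-by-environment effects redrawn each season, independent plot
#' errors, and scalar season/replicate/block nuisance effects. The output is
#' balanced: every (genotype, season, replicate, trait) combination appears
#' exactly once, as required by the combined ANOVA.
#'
#' @param design a [build_design()] object.
#' @param model a [trait_model()] object.
#' @param seed integer seed; output is bit-reproducible given
#'   (design, model, seed).
#' @return A long-format data frame (`plot_table`) with columns
#'   `genotype, season, rep, block, trait, value`.
#' @examples
#' d <- build_design(8, 1, 2, 4, seed = 1)
#' m <- trait_model("Y", mu = 5, sigma_g = matrix(1), sigma_ge = matrix(0),
#'                  sigma_e = matrix(0.2))
#' head(simulate_trial(d, m, seed = 2))
#' @export
simulate_trial <- function(design, model, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "trait_model"))
  traits <- model$trait_names
  k <- length(traits)
  G <- design$n_genotypes
  S <- design$seasons
  R <- design$reps
  sd_g <- sqrt(diag(model$sigma_g))
  scale_t <- ifelse(sd_g > 0, sd_g, 0)

  set.seed(as.integer(seed))
  g_eff <- .mvn_draw(G, model$sigma_g)                      # G x k
  ge_eff <- lapply(seq_len(S), function(s) .mvn_draw(G, model$sigma_ge))
  season_eff <- matrix(stats::rnorm(S * k, 0, 1), S, k) *
    rep(model$season_sd * scale_t, each = S)
  rep_eff <- array(stats::rnorm(S * R * k), c(S, R, k)) *
    rep(model$rep_sd * scale_t, each = S * R)
  n_blk <- design$n_blocks
  block_eff <- array(stats::rnorm(S * R * n_blk * k), c(S, R, n_blk, k)) *
    rep(model$block_sd * scale_t, each = S * R * n_blk)

  plots <- design$plots
  e_eff <- .mvn_draw(nrow(plots), model$sigma_e)            # plots x k

  gi <- match(plots$genotype, design$genotype_ids)
  val <- matrix(0, nrow(plots), k)
  for (j in seq_len(k)) {
    val[, j] <- model$mu[j] +
      season_eff[plots$season, j] +
      rep_eff[cbind(plots$season, plots$rep, j)] +
      block_eff[cbind(plots$season, plots$rep, plots$block, j)] +
      g_eff[gi, j] + e_eff[, j]
    for (s in seq_len(S)) {
      sel <- plots$season == s
      val[sel, j] <- val[sel, j] + ge_eff[[s]][gi[sel], j]
    }
  }

  out <- data.frame(
    genotype = rep(plots$genotype, times = k),
    season = rep(plots$season, times = k),
    rep = rep(plots$rep, times = k),
    block = rep(plots$block, times = k),
    trait = rep(traits, each = nrow(plots)),
    value = as.vector(val),
    stringsAsFactors = FALSE)
  class(out) <- c("plot_table", "data.frame")
  out
}

# Multivariate-normal draw tolerant of semi-definite covariance matrices
# (eigendecomposition square root; fixed draw order keeps runs reproducible).
.mvn_draw <- function(n, sigma) {
  k <- ncol(sigma)
  if (all(sigma == 0)) return(matrix(0, n, k))
  MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma, tol = 1e-6)
}

#' Check that a plot table is balanced
#'
#' A balanced table holds exactly one record per
#' (genotype, season, replicate, trait) combination and only finite values.
#'
#' @param table a long-format plot table.
#' @param traits optional subset of traits to check.
#' @return Invisibly `TRUE`; errors with the missing/duplicated cells
#'   otherwise.
#' @export
check_balance <- function(table, traits = NULL) {
  need <- c("genotype", "season", "rep", "trait", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(traits)) table <- table[table$trait %in% traits, , drop = FALSE]
  if (!nrow(table)) stop("plot table has no rows for the requested traits", call. = FALSE)
  if (any(!is.finite(table$value)))
    stop("plot table contains non-finite values", call. = FALSE)
  cell <- interaction(table$genotype, table$season, table$rep, table$trait,
                      drop = FALSE)
  counts <- table(cell)
  if (any(counts != 1)) {
    bad <- names(counts)[counts != 1][1:min(5, sum(counts != 1))]
    stop("plot table is not balanced; offending (genotype.season.rep.trait) cells: ",
         paste(bad, collapse = "; "),
         if (sum(counts != 1) > 5) " ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}
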