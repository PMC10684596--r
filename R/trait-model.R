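#' Specify the stochastic trait model for a simulated trial
#'
#' The simulator uses the additive random model that underlies combined
#' analysis over environments:
#' \deqn{y = \mu + season + rep + block + G + GE + E}
#' with genotype effects `G ~ MVN(0, sigma_g)`, genotype-by-environment
#' effects `GE ~ MVN(0, sigma_ge)` drawn independently per season, and plot
#' errors `E ~ MVN(0, sigma_e)`, all on the trait scale. Season, replicate
#' and block effects are univariate normal nuisance terms whose magnitudes
#' are expressed as multiples of each trait's genotypic standard deviation
#' (traits carry different units, so absolute scalars would be meaningless
#' across them).
#'
#' @param trait_names unique character vector of trait codes.
#' @param mu named (or positional) numeric vector of trait means.
#' @param sigma_g,sigma_ge,sigma_e trait x trait covariance matrices for the
#'   genotypic, genotype-by-environment and plot-error effects. Must be
#'   symmetric positive semi-definite and share the trait order.
#' @param season_sd,rep_sd,block_sd nuisance-effect magnitudes, as multiples
#'   of the per-trait genotypic SD (0 disables the term).
#' @return An object of class `trait_model`.
#' @examples
#' m <- trait_model(c("A", "B"), mu = c(10, 20),
#'                  sigma_g = diag(2), sigma_ge = 0.25 * diag(2),
#'                  sigma_e = 0.5 * diag(2))
#' @export
trait_model <- function(trait_names, mu, sigma_g, sigma_ge, sigma_e,
                        season_sd = 0, rep_sd = 0, block_sd = 0) {
  k <- length(trait_names)
  if (k < 1 || anyDuplicated(trait_names))
    stop("`trait_names` must be a non-empty set of unique labels", call. = FALSE)
  if (length(mu) != k) stop("`mu` must have one entry per trait", call. = FALSE)
  for (nm in c("sigma_g", "sigma_ge", "sigma_e")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != k))
      stop(sprintf("`%s` must be a %d x %d matrix", nm, k, k), call. = FALSE)
    if (max(abs(m - t(m))) > 1e-8)
      stop(sprintf("`%s` is not symmetric", nm), call. = FALSE)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g)",
                   nm, min(ev)), call. = FALSE)
  }
  structure(list(
    trait_names = as.character(trait_names),
    mu = stats::setNames(as.numeric(mu), trait_names),
    sigma_g = sigma_g, sigma_ge = sigma_ge, sigma_e = sigma_e,
    season_sd = season_sd, rep_sd = rep_sd, block_sd = block_sd),
    class = "trait_model")
}

#' Repair a hand-set correlation matrix to the nearest PSD matrix
#'
#' Clips negative eigenvalues at zero and re-normalizes the result back to a
#' unit diagonal. Used to turn a pairwise-specified (possibly inconsistent)
#' correlation pattern into a valid simulation target.
#'
#' @param R symmetric matrix with unit diagonal.
#' @return A positive semi-definite correlation matrix.
#' @export
repair_correlation <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("Trait model: %d traits (%s%s)\n", length(x$trait_names),
              paste(utils::head(x$trait_names, 6), collapse = ", "),
              if (length(x$trait_names) > 6) ", ..." else ""))
  cat(sprintf("  nuisance magnitudes (x genotypic SD): season %.2f, rep %.2f, block %.2f\n",
              x$season_sd, x$rep_sd, x$block_sd))
  invisible(x)
}
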