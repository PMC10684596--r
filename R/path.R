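#' Direct effects (path coefficients) of predictors on a dependent trait
#'
#' Solves the simultaneous path equations `r_iy = P_i + sum_k r_ik P_k`
#' by inverting the predictor correlation matrix:
#' `direct = Rxx^-1 rxy`. The solution equals the standardized
#' partial-regression coefficients of the dependent on the predictors.
#' A condition-number guard refuses matrices with `CN > 1e6`; screen such
#' predictor sets with [screen_traits()] first.
#'
#' @param Rxx predictor correlation matrix (symmetric, unit diagonal).
#' @param rxy vector of predictor-vs-dependent correlations, same order as
#'   `Rxx`.
#' @return Named vector of direct effects.
#' @examples
#' Rxx <- matrix(c(1, .5, .5, 1), 2, dimnames = rep(list(c("A", "B")), 2))
#' solve_paths(Rxx, c(A = 0.6, B = 0.5))
#' @export
solve_paths <- function(Rxx, rxy) {
  .check_corr(Rxx)
  if (length(rxy) != ncol(Rxx))
    stop("`rxy` must have one correlation per predictor", call. = FALSE)
  if (any(is.na(rxy)))
    stop("`rxy` contains NA (undefined correlations)", call. = FALSE)
  diag_ <- eigen_diagnostics(Rxx)
  if (!is.finite(diag_$condition_number) || diag_$condition_number > 1e6)
    stop("predictor correlation matrix is ill-conditioned (CN = ",
         format(diag_$condition_number),
         "); run the collinearity screen before path analysis", call. = FALSE)
  direct <- solve(Rxx, rxy)
  stats::setNames(as.numeric(direct), .trait_names(Rxx))
}

#' Indirect effects routed through the other predictors
#'
#' Entry `(i, k)` with `i != k` is `r_ik * P_k`: the part of predictor i's
#' correlation with the dependent that flows through predictor k. The
#' diagonal is `NA` (a predictor has no indirect effect via itself). Rows
#' index the trait whose correlation is being decomposed; columns index the
#' route.
#'
#' @param Rxx predictor correlation matrix.
#' @param direct direct-effect vector from [solve_paths()].
#' @return Predictor x predictor matrix of indirect effects, diagonal `NA`.
#' @export
indirect_effects <- function(Rxx, direct) {
  .check_corr(Rxx)
  if (length(direct) != ncol(Rxx))
    stop("`direct` must have one effect per predictor", call. = FALSE)
  out <- Rxx * matrix(direct, nrow(Rxx), ncol(Rxx), byrow = TRUE)
  diag(out) <- NA_real_
  dimnames(out) <- list(.trait_names(Rxx), .trait_names(Rxx))
  out
}

#' Coefficient of determination and residual factor
#'
#' `R2 = sum_i P_i r_iy`; the residual factor `RF = sqrt(1 - R2)` measures
#' the share of dependent-trait variation the predictors leave unexplained.
#' Genotypic-level decompositions built from out-of-range correlations can
#' give `R2 > 1`; then `RF` is undefined (`NA`) and the over-determination
#' flag is set, rather than reporting a complex number.
#'
#' @param direct direct-effect vector.
#' @param rxy predictor-vs-dependent correlations.
#' @return List with `R2`, `RF`, `over_determined`.
#' @examples
#' determination(c(0.98341), c(1))$RF   # 0.12880
#' @export
determination <- function(direct, rxy) {
  if (length(direct) != length(rxy))
    stop("`direct` and `rxy` must have the same length", call. = FALSE)
  R2 <- sum(direct * rxy)
  over <- R2 > 1
  list(R2 = R2, RF = if (over) NA_real_ else sqrt(1 - R2),
       over_determined = over)
}

#' Full path decomposition for one dependent trait
#'
#' Runs [solve_paths()], [indirect_effects()], [determination()] and
#' [percent_table()] and bundles the results. The decomposition satisfies
#' the identity `direct_i + sum_k indirect_ik = r_iy` exactly (up to
#' floating-point error).
#'
#' @param Rxx predictor correlation matrix.
#' @param rxy predictor-vs-dependent correlation vector.
#' @param dependent label of the dependent trait.
#' @param level `"phenotypic"` or `"genotypic"` (bookkeeping only).
#' @return Object of class `path_decomposition` with fields `dependent`,
#'   `predictors`, `level`, `direct`, `indirect`, `r_xy`, `R2`, `RF`,
#'   `over_determined`, `percent`.
#' @export
path_analysis <- function(Rxx, rxy, dependent = "Y",
                          level = c("phenotypic", "genotypic")) {
  level <- match.arg(level)
  direct <- solve_paths(Rxx, rxy)
  indirect <- indirect_effects(Rxx, direct)
  det <- determination(direct, rxy)
  out <- list(dependent = dependent, predictors = .trait_names(Rxx),
              level = level, direct = direct, indirect = indirect,
              r_xy = stats::setNames(as.numeric(rxy), .trait_names(Rxx)),
              R2 = det$R2, RF = det$RF, over_determined = det$over_determined)
  out$percent <- percent_table(out)
  class(out) <- "path_decomposition"
  out
}

#' Percent contribution table
#'
#' Expresses each effect in a predictor's row (its direct effect and its
#' indirect effects via every other predictor) as a percentage of the row's
#' total absolute effect: `100 |e| / (|P_i| + sum_k |indirect_ik|)`. Every
#' row sums to 100.
#'
#' @param decomposition a `path_decomposition` (or a list with `direct` and
#'   `indirect` fields).
#' @return Matrix with the direct percentage on the diagonal and indirect
#'   percentages off-diagonal; rows sum to 100.
#' @export
percent_table <- function(decomposition) {
  direct <- decomposition$direct
  indirect <- decomposition$indirect
  k <- length(direct)
  eff <- indirect
  diag(eff) <- direct
  denom <- rowSums(abs(eff))
  pct <- 100 * abs(eff) / denom
  dimnames(pct) <- dimnames(indirect)
  pct
}

#' Reconstruct predictor-dependent correlations from a decomposition
#'
#' Applies the path identity in reverse: `r_iy = P_i + sum_k indirect_ik`.
#' Serves both as a validity audit of a computed decomposition and as a way
#' to recover the correlations behind a published direct/indirect table.
#'
#' @param decomposition a `path_decomposition` (or list with `direct` and
#'   `indirect`).
#' @return Named vector of reconstructed correlations.
#' @export
reconstruct_correlations <- function(decomposition) {
  decomposition$direct +
    rowSums(decomposition$indirect, na.rm = TRUE)
}

#' @export
print.path_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("%s path decomposition of %s on %d predictors\n",
              x$level, x$dependent, length(x$predictors)))
  cat("Direct effects:\n")
  print(round(x$direct, digits))
  cat(sprintf("R2 = %.5f; residual factor = %s%s\n", x$R2,
              ifelse(is.na(x$RF), "undefined", sprintf("%.5f", x$RF)),
              if (x$over_determined) "  [over-determined: R2 > 1]" else ""))
  invisible(x)
}
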