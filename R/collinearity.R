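#' Variance inflation factors and tolerances
#'
#' For a predictor correlation matrix `R`, `VIF_i` is the i-th diagonal
#' entry of `R^-1` (equivalently `1 / (1 - R^2_i)` from regressing trait i
#' on the others) and `TOL_i = 1 / VIF_i`. A VIF above 10 (TOL below 0.1)
#' signals collinearity severe enough to distort path coefficients.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @return A data frame with columns `trait`, `vif`, `tol`.
#' @examples
#' vif_tol(matrix(c(1, 0.9, 0.9, 1), 2, dimnames = rep(list(c("A", "B")), 2)))
#' @export
vif_tol <- function(R) {
  .check_corr(R)
  inv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; run eigen_diagnostics() and remove the offending traits first",
         call. = FALSE))
  vif <- diag(inv)
  data.frame(trait = .trait_names(R), vif = unname(vif), tol = unname(1 / vif),
             stringsAsFactors = FALSE)
}

#' Eigenvalue diagnostics of a correlation matrix
#'
#' Eigenvalues in descending order, the condition number
#' `CN = lambda_max / lambda_min`, and its severity band: collinearity is
#' weak when CN < 100, moderate when 100 <= CN <= 1000, and severe when
#' CN > 1000. A non-positive smallest eigenvalue gives an infinite CN
#' (severe).
#'
#' @param R symmetric correlation matrix.
#' @return A list with `eigenvalues`, `condition_number`, `severity`.
#' @export
eigen_diagnostics <- function(R) {
  .check_corr(R, require_unit_diag = FALSE)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  cn <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  severity <- if (cn > 1000) "severe" else if (cn >= 100) "moderate" else "weak"
  list(eigenvalues = ev, condition_number = cn, severity = severity)
}

#' Screen traits for multicollinearity
#'
#' Iteratively removes the non-protected trait with the largest VIF until
#' every remaining VIF is at or below `vif_threshold`. Ties are broken by
#' trait-list order (the earlier trait is removed), making the screen
#' deterministic. Each removal is logged with the VIF that triggered it.
#'
#' @param R predictor correlation matrix (>= 2 traits).
#' @param vif_threshold VIF ceiling; the conventional default is 10.
#' @param protected traits that may never be removed (e.g. the dependent
#'   yields of a planned path analysis).
#' @return An object of class `collinearity_report`: final `vif`/`tol`
#'   table, eigenvalue diagnostics of the retained matrix, `removed`
#'   (ordered data frame of trait + VIF at removal), `retained`, and the
#'   threshold used.
#' @export
screen_traits <- function(R, vif_threshold = 10, protected = character()) {
  .check_corr(R)
  traits <- .trait_names(R)
  dimnames(R) <- list(traits, traits)
  if (length(traits) < 2) stop("need at least 2 traits to screen", call. = FALSE)
  missing_prot <- setdiff(protected, traits)
  if (length(missing_prot))
    stop("protected trait(s) not in matrix: ",
         paste(missing_prot, collapse = ", "), call. = FALSE)
  keep <- traits
  removed <- data.frame(trait = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    vt <- vif_tol(R[keep, keep, drop = FALSE])
    candidates <- vt[!(vt$trait %in% protected), , drop = FALSE]
    if (!nrow(candidates) || max(vt$vif) <= vif_threshold) {
      if (max(vt$vif) > vif_threshold && !nrow(candidates))
        stop("all remaining traits are protected but max VIF (",
             sprintf("%.2f", max(vt$vif)), ") still exceeds the threshold ",
             vif_threshold, call. = FALSE)
      if (max(vt$vif) > vif_threshold && max(candidates$vif) <= vif_threshold)
        stop("only protected trait(s) exceed the VIF threshold ",
             vif_threshold, "; cannot screen further", call. = FALSE)
      break
    }
    # first candidate within floating-point reach of the maximum: exact ties
    # resolve by trait-list order
    i_worst <- which(candidates$vif >= max(candidates$vif) * (1 - 1e-10))[1]
    worst <- candidates$trait[i_worst]
    removed <- rbind(removed, data.frame(
      trait = worst, vif = candidates$vif[i_worst], stringsAsFactors = FALSE))
    keep <- setdiff(keep, worst)
    if (length(keep) < 2) break
  }
  final <- vif_tol(R[keep, keep, drop = FALSE])
  out <- list(vif = final, eigen = eigen_diagnostics(R[keep, keep, drop = FALSE]),
              removed = removed, retained = keep,
              vif_threshold = vif_threshold, protected = protected)
  class(out) <- "collinearity_report"
  out
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("Multicollinearity screen (VIF threshold %s): %d trait(s) removed, %d retained\n",
              format(x$vif_threshold), nrow(x$removed), length(x$retained)))
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  removed %-5s (VIF %.2f at removal)\n",
                  x$removed$trait[i], x$removed$vif[i]))
  }
  cat(sprintf("  retained set: max VIF %.2f, condition number %.1f (%s)\n",
              max(x$vif$vif), x$eigen$condition_number, x$eigen$severity))
  invisible(x)
}

.trait_names <- function(R) {
  nm <- colnames(R)
  if (is.null(nm)) nm <- paste0("T", seq_len(ncol(R)))
  nm
}

.check_corr <- function(R, require_unit_diag = TRUE) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("`R` must be a square matrix", call. = FALSE)
  if (any(is.na(R)))
    stop("`R` contains NA entries (undefined correlations); screen or clamp first",
         call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8)
    stop("`R` must be symmetric", call. = FALSE)
  if (require_unit_diag && max(abs(diag(R) - 1)) > 1e-8)
    stop("`R` must have a unit diagonal", call. = FALSE)
  invisible(TRUE)
}
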