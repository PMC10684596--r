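#' Significance mark for a correlation coefficient
#'
#' Two-sided test of `r = 0` using `t = r * sqrt((n-2)/(1-r^2))` against the
#' t distribution with `n - 2` degrees of freedom, where `n` is the number
#' of genotypes. Marks are `*`, `**`, `***` at the 5, 1 and 0.1 percent
#' probability levels and `ns` otherwise; `|r| >= 1` is marked `***` by
#' convention.
#'
#' @param r correlation coefficient(s); vectorized.
#' @param n number of genotypes (>= 3).
#' @return Character vector of marks in `{ns, *, **, ***}` (`NA` for `NA`
#'   input).
#' @examples
#' correlation_significance(c(0.18, 0.30), n = 120)
#' @export
correlation_significance <- function(r, n) {
  if (n < 3) stop("significance test needs n >= 3 genotypes", call. = FALSE)
  out <- rep(NA_character_, length(r))
  ok <- !is.na(r)
  a <- abs(r[ok])
  p <- ifelse(a >= 1, 0,
              2 * stats::pt(a * sqrt((n - 2) / (1 - a^2)), df = n - 2,
                            lower.tail = FALSE))
  out[ok] <- ifelse(p <= 0.001, "***",
             ifelse(p <= 0.01, "**",
             ifelse(p <= 0.05, "*", "ns")))
  out
}

.corr_estimate <- function(r, level, traits, n, out_of_range = FALSE,
                           reason = NULL) {
  structure(list(r = r, level = level, traitX = traits[1], traitY = traits[2],
                 n = n,
                 significance = if (is.na(r)) NA_character_
                                else correlation_significance(r, n),
                 out_of_range_flag = out_of_range, reason = reason),
            class = "correlation_estimate")
}

#' Phenotypic correlation from variance components
#'
#' `rp = cov_p / sqrt(s2p_x * s2p_y)`, using the phenotypic (mean-basis)
#' covariance and variances of an [estimate_components()] result.
#'
#' @param comp a `component_estimates` object.
#' @return A `correlation_estimate` with significance mark at `n - 2` df.
#' @export
phenotypic_correlation <- function(comp) {
  stopifnot(inherits(comp, "component_estimates"))
  vp <- comp$var_p
  if (any(vp <= 0)) {
    bad <- comp$traits[vp <= 0][1]
    stop("phenotypic variance is zero for trait `", bad,
         "`; correlation undefined", call. = FALSE)
  }
  r <- comp$cov_p / sqrt(vp[1] * vp[2])
  .corr_estimate(unname(r), "phenotypic", comp$traits, comp$n_genotypes)
}

#' Genotypic correlation from variance components
#'
#' `rg = cov_g / sqrt(s2g_x * s2g_y)`. Because the components are
#' method-of-moments estimates, `|rg|` may exceed 1; such values are
#' reported with `out_of_range_flag = TRUE` rather than clamped (a clamp is
#' available downstream). A genotypic variance clipped to zero makes the
#' correlation undefined; the estimate then carries `r = NA` and the
#' truncation reason.
#'
#' @param comp a `component_estimates` object.
#' @param clamp if `TRUE`, clamp `r` into `[-1, 1]`.
#' @return A `correlation_estimate`.
#' @export
genotypic_correlation <- function(comp, clamp = FALSE) {
  stopifnot(inherits(comp, "component_estimates"))
  vg <- comp$var_g
  if (any(vg <= 0)) {
    bad <- comp$traits[vg <= 0][1]
    return(.corr_estimate(NA_real_, "genotypic", comp$traits,
                          comp$n_genotypes,
                          reason = paste0("genotypic variance of `", bad,
                                          "` is zero (clipped negative estimate)")))
  }
  r <- unname(comp$cov_g / sqrt(vg[1] * vg[2]))
  oor <- abs(r) > 1
  if (clamp) r <- max(-1, min(1, r))
  .corr_estimate(r, "genotypic", comp$traits, comp$n_genotypes,
                 out_of_range = oor)
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("%s correlation r(%s, %s) = %s %s (n = %d)%s\n",
              x$level, x$traitX, x$traitY,
              ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)),
              ifelse(is.na(x$significance), "", x$significance), x$n,
              if (isTRUE(x$out_of_range_flag)) "  [|r| > 1]" else ""))
  if (!is.null(x$reason)) cat("  undefined: ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Phenotypic and genotypic correlation matrices
#'
#' Estimates variance and covariance components for every trait pair of a
#' balanced plot table and assembles the phenotypic and genotypic
#' correlation matrices with their significance marks (the classic
#' "phenotypic above / genotypic below the diagonal" table).
#'
#' @inheritParams mean_squares
#' @param traits character vector (>= 2) of trait codes to correlate.
#' @param basis phenotypic-variance basis passed to [estimate_components()].
#' @param clamp clamp out-of-range genotypic correlations into `[-1, 1]`.
#' @return An object of class `correlation_pair`: trait order, `rp` and `rg`
#'   matrices, significance matrices `sig_p`/`sig_g`, out-of-range and
#'   undefined flags, and the genotype count `n`.
#' @export
correlation_matrices <- function(table, traits, blocks = c("ignore", "absorb"),
                                 basis = c("mean", "plot"), clamp = FALSE) {
  blocks <- match.arg(blocks)
  basis <- match.arg(basis)
  if (length(traits) < 2) stop("need at least 2 traits", call. = FALSE)
  if (blocks == "ignore") {
    w <- .trial_wide(table, traits)
    st <- .strata_cp(w)
    if (w$S < 2 || w$R < 2)
      stop("component estimation needs at least 2 environments and 2 reps",
           call. = FALSE)
    R <- w$R; S <- w$S
    M <- mapply(function(cp, df) cp / df, st$cp, st$df, SIMPLIFY = FALSE)
    C_e <- M$error
    C_ge <- (M$genotype_x_environment - M$error) / R
    C_g <- (M$genotype - M$genotype_x_environment) / (R * S)
    n <- w$G
  } else {
    k <- length(traits)
    C_g <- C_ge <- C_e <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
    n <- NULL; S <- NULL; R <- NULL
    ms_list <- lapply(traits, function(t) mean_squares(table, t, blocks = blocks))
    names(ms_list) <- traits
    for (i in seq_len(k)) for (j in i:k) {
      mcp <- if (i == j) ms_list[[i]] else
        mean_cross_products(table, traits[i], traits[j], blocks = blocks)
      comp <- estimate_components(ms_list[[i]], ms_list[[j]], mcp, basis = basis)
      # unclipped ladder values for matrix assembly
      C_g[i, j] <- C_g[j, i] <- comp$cov_g
      C_ge[i, j] <- C_ge[j, i] <- comp$cov_ge
      C_e[i, j] <- C_e[j, i] <- comp$cov_e
      n <- comp$n_genotypes; S <- comp$n_environments; R <- comp$n_reps
    }
  }
  if (basis == "mean") {
    C_p <- C_g + C_ge / S + C_e / (R * S)
  } else {
    C_p <- C_g + C_ge + C_e
  }

  to_corr <- function(C, clip_diag = FALSE) {
    d <- diag(C)
    if (clip_diag) d <- pmax(d, 0)
    ok <- d > 0
    Rm <- matrix(NA_real_, nrow(C), ncol(C), dimnames = dimnames(C))
    sc <- sqrt(d)
    Rm[ok, ok] <- C[ok, ok] / tcrossprod(sc[ok])
    diag(Rm)[ok] <- 1
    Rm
  }
  rp <- to_corr(C_p)
  rg <- to_corr(C_g, clip_diag = TRUE)
  oor <- !is.na(rg) & abs(rg) > 1
  if (clamp) rg <- pmin(1, pmax(-1, rg))

  sig <- function(Rm) {
    out <- matrix(NA_character_, nrow(Rm), ncol(Rm), dimnames = dimnames(Rm))
    out[] <- correlation_significance(as.vector(Rm), n)
    diag(out) <- ""
    out
  }
  out <- list(traits = traits, n = n, seasons = S, reps = R, basis = basis,
              rp = rp, rg = rg, sig_p = sig(rp), sig_g = sig(rg),
              rg_out_of_range = oor,
              rg_undefined = is.na(diag(rg)))
  class(out) <- "correlation_pair"
  out
}

#' @export
print.correlation_pair <- function(x, digits = 2, ...) {
  cat(sprintf("Phenotypic (above diagonal) and genotypic (below diagonal) correlations, %d traits, n = %d genotypes\n",
              length(x$traits), x$n))
  cat(format_correlation_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render a combined correlation table
#'
#' Formats a [correlation_matrices()] result as plain text with phenotypic
#' correlations (with stars) above the diagonal and genotypic below.
#'
#' @param x a `correlation_pair` object.
#' @param digits decimals for the coefficients.
#' @return Character vector of text lines.
#' @export
format_correlation_table <- function(x, digits = 2) {
  k <- length(x$traits)
  cells <- matrix("", k + 1, k + 1)
  cells[1, ] <- c("", x$traits)
  cells[, 1] <- c("", x$traits)
  fmt <- function(r, s) {
    if (is.na(r)) return("NA")
    paste0(formatC(r, digits = digits, format = "f"),
           if (!is.na(s) && s != "ns" && nzchar(s)) s else
             if (identical(s, "ns")) " ns" else "")
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cells[i + 1, j + 1] <-
      if (i == j) "1" else
      if (i < j) fmt(x$rp[i, j], x$sig_p[i, j]) else
        fmt(x$rg[i, j], x$sig_g[i, j])
  }
  widths <- apply(nchar(cells), 2, max)
  apply(cells, 1, function(row)
    paste(mapply(formatC, row, width = widths), collapse = "  "))
}
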