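# Combined-over-environments ANOVA/ANCOVA machinery.
#
# Model: value = mean + environment + rep(environment) + genotype
#               + genotype x environment + error
# On a balanced table all strata are orthogonal, so sums of squares (and,
# by polarization, sums of cross-products) come from closed-form stratum
# means. Incomplete blocks are ignored by default (RCBD approximation); they
# can be absorbed as a nuisance stratum via sequential least squares.

# Wide layout: plots x traits value matrix plus the classification factors.
.trial_wide <- function(table, traits) {
  check_balance(table, traits)
  sub <- table[table$trait %in% traits, , drop = FALSE]
  g <- factor(sub$genotype)
  s <- factor(sub$season)
  r <- factor(sub$rep)
  key <- interaction(sub$genotype, sub$season, sub$rep, drop = TRUE)
  first <- !duplicated(paste(sub$trait, key))
  # order plots consistently: one row per (g, s, r)
  plot_id <- levels(key)
  Y <- matrix(NA_real_, length(plot_id), length(traits),
              dimnames = list(plot_id, traits))
  Y[cbind(match(key, plot_id), match(sub$trait, traits))] <- sub$value
  idx <- match(plot_id, key)
  list(Y = Y,
       g = g[idx], s = s[idx], r = r[idx],
       block = if ("block" %in% names(sub)) sub$block[idx] else NULL,
       G = nlevels(g), S = nlevels(s), R = nlevels(r))
}

# Stratum cross-product matrices (trait x trait) and degrees of freedom.
.strata_cp <- function(w) {
  Y <- w$Y
  G <- w$G; S <- w$S; R <- w$R
  n <- nrow(Y)
  m <- colMeans(Y)
  Yc <- sweep(Y, 2, m)
  cp_total <- crossprod(Yc)

  mg <- rowsum(Y, w$g) / (S * R)
  cp_g <- S * R * crossprod(sweep(mg, 2, m))

  ms <- rowsum(Y, w$s) / (G * R)
  cp_env <- G * R * crossprod(sweep(ms, 2, m))

  sr <- interaction(w$s, w$r, drop = TRUE)
  msr <- rowsum(Y, sr) / G
  s_of_sr <- w$s[match(levels(sr), sr)]
  cp_rep <- G * crossprod(msr - ms[s_of_sr, , drop = FALSE])

  gs <- interaction(w$g, w$s, drop = TRUE)
  mgs <- rowsum(Y, gs) / R
  g_of_gs <- w$g[match(levels(gs), gs)]
  s_of_gs <- w$s[match(levels(gs), gs)]
  dev <- mgs - mg[g_of_gs, , drop = FALSE] - ms[s_of_gs, , drop = FALSE] +
    matrix(m, nrow(mgs), ncol(Y), byrow = TRUE)
  cp_ge <- R * crossprod(dev)

  cp_e <- cp_total - cp_g - cp_env - cp_rep - cp_ge

  list(cp = list(environment = cp_env, rep_within_env = cp_rep,
                 genotype = cp_g, genotype_x_environment = cp_ge,
                 error = cp_e),
       df = c(environment = S - 1, rep_within_env = S * (R - 1),
              genotype = G - 1, genotype_x_environment = (G - 1) * (S - 1),
              error = S * (G - 1) * (R - 1)),
       G = G, S = S, R = R)
}

# Sequential (Type-I) stratum sums via lm(), with incomplete blocks absorbed
# before genotype. Used only when blocks = "absorb"; cross-products by
# polarization: SCP = (SS(x + y) - SS(x) - SS(y)) / 2.
.strata_absorb_ss <- function(y, w) {
  d <- data.frame(y = y, g = w$g, s = w$s, r = w$r,
                  b = factor(w$block))
  fit <- stats::lm(y ~ s + s:r + s:r:b + g + s:g, data = d)
  a <- stats::anova(fit)
  ss <- stats::setNames(a[["Sum Sq"]], rownames(a))
  c(environment = unname(ss["s"]),
    rep_within_env = unname(ss["s:r"]),
    block_within_rep = unname(ss["s:r:b"]),
    genotype = unname(ss["g"]),
    genotype_x_environment = unname(ss["s:g"]),
    error = unname(ss["Residuals"]))
}

.anova_table <- function(sources, df, ms, meta) {
  out <- data.frame(source = sources, df = as.integer(df), ms = as.numeric(ms),
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  class(out) <- c("anova_strata", "data.frame")
  out
}

#' Stratum mean squares for one trait
#'
#' Computes the combined-over-environments ANOVA mean squares for a single
#' trait on a balanced plot table. By default incomplete blocks are ignored
#' (randomized-complete-block approximation); with `blocks = "absorb"` the
#' block-within-replicate stratum is removed by sequential least squares
#' before the genotype sum of squares.
#'
#' @param table balanced long-format plot table.
#' @param trait trait code to analyse.
#' @param blocks `"ignore"` (default) or `"absorb"`.
#' @return An `anova_strata` data frame with columns `source`, `df`, `ms`
#'   and metadata attributes (genotype/season/rep counts, traits).
#' @examples
#' d <- build_design(6, 2, 2, 3, seed = 1)
#' m <- trait_model("Y", 10, matrix(1), matrix(0.2), matrix(0.5))
#' mean_squares(simulate_trial(d, m, seed = 2), "Y")
#' @export
mean_squares <- function(table, trait, blocks = c("ignore", "absorb")) {
  blocks <- match.arg(blocks)
  mean_cross_products(table, trait, trait, blocks = blocks)
}

#' Stratum mean cross-products for a pair of traits
#'
#' Same strata as [mean_squares()] with squared deviations replaced by
#' cross-deviations; `mean_cross_products(t, t)` coincides with
#' `mean_squares(t)`. These are the ANCOVA inputs from which genotypic and
#' phenotypic covariance components are estimated.
#'
#' @inheritParams mean_squares
#' @param traitX,traitY trait codes.
#' @return An `anova_strata` data frame of mean cross-products.
#' @export
mean_cross_products <- function(table, traitX, traitY,
                                blocks = c("ignore", "absorb")) {
  blocks <- match.arg(blocks)
  traits <- unique(c(traitX, traitY))
  w <- .trial_wide(table, traits)
  if (blocks == "absorb" && is.null(w$block))
    stop("blocks = \"absorb\" requires a `block` column", call. = FALSE)
  if (blocks == "ignore") {
    st <- .strata_cp(w)
    cp <- vapply(st$cp, function(m) m[traitX, traitY], numeric(1))
    df <- st$df
  } else {
    x <- w$Y[, traitX]
    y <- w$Y[, traitY]
    ss_x <- .strata_absorb_ss(x, w)
    if (traitX == traitY) {
      cp <- ss_x
    } else {
      ss_y <- .strata_absorb_ss(y, w)
      ss_xy <- .strata_absorb_ss(x + y, w)
      cp <- (ss_xy - ss_x - ss_y) / 2
    }
    G <- w$G; S <- w$S; R <- w$R
    n_blk <- length(unique(w$block))
    df <- c(environment = S - 1, rep_within_env = S * (R - 1),
            block_within_rep = S * R * (n_blk - 1),
            genotype = G - 1, genotype_x_environment = (G - 1) * (S - 1),
            error = NA)
    df["error"] <- nrow(w$Y) - 1 - sum(df[-length(df)])
  }
  ms <- ifelse(df > 0, cp / df, NA_real_)
  .anova_table(names(df), df, ms,
               meta = list(n_genotypes = w$G, n_environments = w$S,
                           n_reps = w$R, traitX = traitX, traitY = traitY,
                           blocks = blocks))
}

.ms_of <- function(tab, src) {
  i <- match(src, tab$source)
  if (is.na(i)) stop("stratum `", src, "` missing from ANOVA table", call. = FALSE)
  tab$ms[i]
}

#' Method-of-moments variance and covariance components for a trait pair
#'
#' Solves the expected-mean-squares ladder of the combined random model
#' (`E[MS_e] = s2e`, `E[MS_ge] = s2e + r s2ge`,
#' `E[MS_g] = s2e + r s2ge + r s s2g`) for the genotypic,
#' genotype-by-environment and error components of both traits and of their
#' cross-products. Negative variance components are clipped at zero and
#' flagged; covariance components are left signed. Phenotypic terms follow
#' the genotype-mean basis by default
#' (`s2p = s2g + s2ge/s + s2e/(r s)`), with a plot basis
#' (`s2g + s2ge + s2e`) available.
#'
#' @param msX,msY [mean_squares()] tables of the two traits.
#' @param mcp [mean_cross_products()] table of the pair.
#' @param basis `"mean"` (genotype-mean phenotypic variance, default) or
#'   `"plot"`.
#' @return An object of class `component_estimates`: per-trait `var_g`,
#'   `var_ge`, `var_e`, `var_p`; pair `cov_g`, `cov_ge`, `cov_e`, `cov_p`;
#'   truncation flags; design metadata.
#' @export
estimate_components <- function(msX, msY, mcp, basis = c("mean", "plot")) {
  basis <- match.arg(basis)
  mx <- attr(msX, "meta"); my <- attr(msY, "meta"); mp <- attr(mcp, "meta")
  for (nm in c("n_genotypes", "n_environments", "n_reps")) {
    if (!(identical(mx[[nm]], my[[nm]]) && identical(mx[[nm]], mp[[nm]])))
      stop("inconsistent `", nm, "` across ANOVA tables", call. = FALSE)
  }
  S <- mx$n_environments
  R <- mx$n_reps
  if (S < 2 || R < 2)
    stop("component estimation needs at least 2 environments and 2 reps",
         call. = FALSE)

  ladder <- function(tab) {
    e <- .ms_of(tab, "error")
    ge <- (.ms_of(tab, "genotype_x_environment") - e) / R
    g <- (.ms_of(tab, "genotype") - .ms_of(tab, "genotype_x_environment")) / (R * S)
    c(g = g, ge = ge, e = e)
  }
  cx <- ladder(msX)
  cy <- ladder(msY)
  cc <- ladder(mcp)

  clip <- function(v) pmax(v, 0)
  truncated <- rbind(x = cx < 0, y = cy < 0)
  colnames(truncated) <- c("g", "ge", "e")
  vx <- clip(cx); vy <- clip(cy)
  phen <- function(v) {
    if (basis == "mean") v["g"] + v["ge"] / S + v["e"] / (R * S)
    else sum(v)
  }
  out <- list(
    traits = c(mx$traitX, my$traitX),
    n_genotypes = mx$n_genotypes, n_environments = S, n_reps = R,
    basis = basis,
    var_g = stats::setNames(c(vx["g"], vy["g"]), c(mx$traitX, my$traitX)),
    var_ge = stats::setNames(c(vx["ge"], vy["ge"]), c(mx$traitX, my$traitX)),
    var_e = stats::setNames(c(vx["e"], vy["e"]), c(mx$traitX, my$traitX)),
    var_p = stats::setNames(c(phen(vx), phen(vy)), c(mx$traitX, my$traitX)),
    cov_g = unname(cc["g"]), cov_ge = unname(cc["ge"]), cov_e = unname(cc["e"]),
    cov_p = unname(phen(cc)),
    truncated = truncated)
  class(out) <- "component_estimates"
  out
}

#' @export
print.component_estimates <- function(x, ...) {
  cat(sprintf("Variance/covariance components for (%s, %s), %d genotypes x %d env x %d reps [%s basis]\n",
              x$traits[1], x$traits[2], x$n_genotypes, x$n_environments,
              x$n_reps, x$basis))
  tab <- rbind(var_g = x$var_g, var_ge = x$var_ge, var_e = x$var_e,
               var_p = x$var_p)
  print(round(tab, 5))
  cat(sprintf("cov_g = %.5f, cov_ge = %.5f, cov_e = %.5f, cov_p = %.5f\n",
              x$cov_g, x$cov_ge, x$cov_e, x$cov_p))
  if (any(x$truncated)) cat("note: negative variance component(s) clipped at zero\n")
  invisible(x)
}
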