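#' Registry of the 24 amaranth agro-morphological traits
#'
#' Marker codes, units and simulation scales for the 24 quantitative traits
#' of the reference amaranth evaluation: 16 analysis traits with low mutual
#' collinearity plus 8 traits (TSW, GFP, BLBL, TLBL, SD, NN, PL, LT) that
#' are near-linear combinations of the others and are expected to fall to
#' the multicollinearity screen.
#'
#' @return A data frame with columns `code`, `trait`, `unit`, `mean`,
#'   `sd_g` (genotypic SD used by the simulator).
#' @export
amaranth_traits <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code  trait                                   unit          mean  sd_g
LW    'leaf width'                            cm             8.0  0.80
AIL   'axillary inflorescence length'         cm            10.0  1.20
PHM   'plant height at maturity'              cm           120.0 12.00
BN    'branch number'                         count         12.0  1.50
LL    'leaf length'                           cm            14.0  1.40
TISL  'terminal inflorescence stalk length'   cm            30.0  3.50
TILL  'terminal inflorescence laterals length' cm           25.0  3.00
LN    'leaf number'                           count         32.0  4.00
PHF   'plant height at flowering'             cm            85.0  9.00
DM    'days to maturity'                      days         105.0  6.00
LA    'leaf area'                             cm2           70.0  9.00
DF    'days to flowering'                     days          62.0  5.00
DE    'days to emergence'                     days           7.0  0.80
GY    'grain yield'                           t/ha           1.8  0.25
LY    'leaf yield'                            t/ha           2.4  0.30
GSFR  'grain sink filling rate'               kg/ha/day     45.0  6.00
TSW   '1000 seed weight'                      g              0.8  0.10
GFP   'grain filling period'                  days          43.0  3.50
BLBL  'basal lateral branch length'           cm            35.0  4.00
TLBL  'top lateral branch length'             cm            22.0  2.50
SD    'stem diameter'                         cm             1.6  0.18
NN    'node number'                           count         18.0  2.00
PL    'petiole length'                        cm             6.0  0.70
LT    'leaf thickness'                        mm             0.45 0.05
")
  df
}

# Hand-set genotypic correlation pattern among the 16 analysis traits,
# mirroring the strong relations of the reference study (leaf-size cluster
# LW-LL-LA, inflorescence cluster AIL-TILL-TISL, architecture/phenology
# cluster PHM-PHF-BN-DM-DF, and the tight GY-GSFR link). Unstated pairs are
# left at zero and the whole matrix is spectrally repaired.
.amaranth_r16 <- function() {
  tr <- c("LW", "AIL", "PHM", "BN", "LL", "TISL", "TILL", "LN",
          "PHF", "DM", "LA", "DF", "DE", "GY", "LY", "GSFR")
  R <- diag(length(tr))
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("LW", "LL", 0.90);  set_r("LW", "LA", 0.77);  set_r("LW", "DF", 0.61)
  set_r("LW", "PHF", 0.48); set_r("LW", "PHM", 0.45); set_r("LW", "LY", 0.43)
  set_r("LW", "GY", 0.18);  set_r("LW", "LN", 0.30);  set_r("LW", "AIL", -0.15)
  set_r("LW", "DE", -0.15); set_r("LW", "TISL", -0.10); set_r("LW", "BN", 0.10)
  set_r("LW", "DM", 0.10);  set_r("LW", "GSFR", 0.10)
  set_r("AIL", "TILL", 0.86); set_r("AIL", "TISL", 0.80); set_r("AIL", "GSFR", 0.30)
  set_r("AIL", "PHM", -0.56); set_r("AIL", "BN", -0.50);  set_r("AIL", "LN", -0.35)
  set_r("AIL", "PHF", -0.54); set_r("AIL", "DM", -0.42);  set_r("AIL", "DF", -0.64)
  set_r("AIL", "DE", -0.21);  set_r("AIL", "LY", -0.19);  set_r("AIL", "GY", 0.38)
  set_r("AIL", "LL", -0.20)
  set_r("PHM", "BN", 0.74);  set_r("PHM", "PHF", 0.78); set_r("PHM", "DM", 0.52)
  set_r("PHM", "LL", 0.50);  set_r("PHM", "DE", 0.42);  set_r("PHM", "LY", 0.29)
  set_r("PHM", "LN", 0.50);  set_r("PHM", "DF", 0.45);  set_r("PHM", "TILL", -0.45)
  set_r("PHM", "TISL", -0.25); set_r("PHM", "GY", -0.10); set_r("PHM", "GSFR", 0.19)
  set_r("BN", "LN", 0.39);   set_r("BN", "PHF", 0.66);  set_r("BN", "DM", 0.70)
  set_r("BN", "DF", 0.58);   set_r("BN", "DE", 0.58);   set_r("BN", "TILL", -0.48)
  set_r("BN", "TISL", -0.18); set_r("BN", "GSFR", -0.36); set_r("BN", "LY", 0.23)
  set_r("BN", "GY", -0.24);  set_r("BN", "LL", 0.15)
  set_r("LL", "PHF", 0.56);  set_r("LL", "LA", 0.76);  set_r("LL", "DF", 0.62)
  set_r("LL", "GSFR", 0.29); set_r("LL", "DE", -0.19); set_r("LL", "LY", 0.40)
  set_r("LL", "GY", 0.21);   set_r("LL", "TILL", -0.10); set_r("LL", "TISL", -0.10)
  set_r("LL", "LN", 0.35);   set_r("LL", "DM", 0.15)
  set_r("TISL", "TILL", 0.78); set_r("TISL", "GY", 0.38);  set_r("TISL", "LY", -0.21)
  set_r("TISL", "GSFR", 0.25); set_r("TISL", "PHF", -0.40); set_r("TISL", "DM", -0.30)
  set_r("TISL", "DF", -0.45);  set_r("TISL", "DE", -0.15);  set_r("TISL", "LN", -0.25)
  set_r("TILL", "GSFR", 0.44); set_r("TILL", "GY", 0.51);  set_r("TILL", "LY", -0.19)
  set_r("TILL", "PHF", -0.45); set_r("TILL", "DM", -0.35); set_r("TILL", "DF", -0.50)
  set_r("TILL", "DE", -0.20);  set_r("TILL", "LN", -0.30)
  set_r("LN", "GY", -0.30); set_r("LN", "GSFR", -0.31); set_r("LN", "LY", 0.20)
  set_r("LN", "DM", 0.32);  set_r("LN", "DF", 0.28);    set_r("LN", "DE", -0.30)
  set_r("LN", "LA", -0.24); set_r("LN", "PHF", 0.30)
  set_r("PHF", "DM", 0.60); set_r("PHF", "LA", 0.32); set_r("PHF", "DF", 0.82)
  set_r("PHF", "DE", 0.32); set_r("PHF", "LY", 0.37); set_r("PHF", "GY", -0.10)
  set_r("DM", "DF", 0.60);  set_r("DM", "DE", 0.36);  set_r("DM", "GSFR", -0.48)
  set_r("DM", "GY", -0.28); set_r("DM", "LY", 0.10)
  set_r("LA", "DF", 0.47);  set_r("LA", "DE", -0.34); set_r("LA", "LY", 0.45)
  set_r("LA", "GY", 0.10);  set_r("LA", "GSFR", 0.10)
  set_r("DF", "LY", 0.41);  set_r("DF", "GY", 0.12);  set_r("DF", "GSFR", -0.15)
  set_r("DF", "DE", -0.22)
  set_r("DE", "LY", -0.10); set_r("DE", "GY", -0.10); set_r("DE", "GSFR", -0.20)
  set_r("GY", "GSFR", 0.90); set_r("GY", "LY", 0.20)
  set_r("LY", "GSFR", 0.18)
  R
}

# PSD target for the 16-trait pattern. Plain eigenvalue clipping leaves the
# matrix singular and distorts the headline pairs, so the repair alternates
# clipping (floor 0.10, keeping the matrix invertible for VIF work) with
# restoration of the anchor correlations that define the fixture's clusters.
.amaranth_r16_target <- function() {
  clip <- function(R, floor) {
    e <- eigen(R, symmetric = TRUE)
    vals <- pmax(e$values, floor)
    out <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    diag(out) <- 1
    dimnames(out) <- dimnames(R)
    (out + t(out)) / 2
  }
  anchors <- list(
    c("LW", "LL", 0.90), c("GY", "GSFR", 0.90), c("LW", "LA", 0.77),
    c("LL", "LA", 0.76), c("AIL", "TILL", 0.86), c("AIL", "TISL", 0.80),
    c("TISL", "TILL", 0.78), c("PHF", "DF", 0.82))
  R <- .amaranth_r16()
  for (it in 1:8) {
    R <- clip(R, 0.10)
    for (a in anchors) R[a[1], a[2]] <- R[a[2], a[1]] <- as.numeric(a[3])
  }
  R
}

# Each collinear trait is an even-weight combination of a positively
# inter-correlated set of analysis-trait partners, scaled so its multiple
# R^2 on the 16-trait set is `r2`. Its VIF (~1/(1-r2)) then dominates every
# partner's at each step of the screen, so the eight fall first.
.amaranth_collinear_partners <- function() {
  list(
    LT   = c("LW", "LL", "LA"),
    PL   = c("LL", "LA", "PHF"),
    SD   = c("PHM", "BN", "PHF"),
    NN   = c("LN", "BN", "PHM"),
    BLBL = c("DM", "DE", "LN"),
    TLBL = c("DF", "DM", "PHM"),
    TSW  = c("GY", "GSFR", "TILL"),
    GFP  = c("DM", "DF", "BN"))
}

#' Target genotypic correlation matrix of the amaranth fixture
#'
#' Builds the 24x24 genotypic correlation matrix the simulator reproduces:
#' a hand-set 16-trait pattern, spectrally repaired to a well-conditioned
#' positive-definite matrix while preserving its anchor correlations,
#' extended with 8 traits constructed as noisy combinations of two or three
#' partner traits with multiple R^2 = `r2`, giving them the strong
#' collinearity the screen is meant to catch.
#'
#' @param r2 multiple R^2 of each collinear trait on the analysis set
#'   (default 0.95, i.e. a population VIF of 20).
#' @return A PSD correlation matrix over the 24 [amaranth_traits()] codes.
#' @export
amaranth_correlations <- function(r2 = 0.95) {
  R16 <- .amaranth_r16_target()
  tr16 <- colnames(R16)
  partners <- .amaranth_collinear_partners()
  codes <- amaranth_traits()$code
  # loading matrix B: rows = 24 traits, cols = 16 analysis traits
  B <- matrix(0, length(codes), length(tr16), dimnames = list(codes, tr16))
  B[tr16, tr16] <- diag(length(tr16))
  uniq <- stats::setNames(numeric(length(codes)), codes)
  for (tt in names(partners)) {
    p <- partners[[tt]]
    w <- rep(1, length(p))
    scale <- sqrt(r2 / drop(t(w) %*% R16[p, p] %*% w))
    B[tt, p] <- w * scale
    uniq[tt] <- 1 - r2
  }
  R <- B %*% R16 %*% t(B) + diag(uniq)
  dimnames(R) <- list(codes, codes)
  (R + t(R)) / 2
}

#' Trait model of the reference amaranth trial
#'
#' Assembles the [trait_model()] used by [amaranth_fixture()]: 24 traits,
#' genotypic covariance from [amaranth_correlations()] scaled by the
#' per-trait genotypic SDs of [amaranth_traits()], and proportional
#' genotype-by-environment and plot-error covariances
#' (`sigma_ge = 0.25 sigma_g`, `sigma_e = 0.5 sigma_g`). Under the
#' mean-basis convention with 2 seasons and 2 reps this makes the
#' phenotypic correlation matrix equal the configured genotypic one and
#' gives a mean-basis heritability of 0.8 for every trait.
#'
#' @param ge_prop,e_prop proportionality constants for `sigma_ge` and
#'   `sigma_e` relative to `sigma_g`.
#' @inheritParams trait_model
#' @return A `trait_model` over the 24 amaranth traits.
#' @export
amaranth_model <- function(ge_prop = 0.25, e_prop = 0.5,
                           season_sd = 0.5, rep_sd = 0.2, block_sd = 0.3) {
  reg <- amaranth_traits()
  R <- amaranth_correlations()
  D <- reg$sd_g
  sigma_g <- R * tcrossprod(D)
  dimnames(sigma_g) <- list(reg$code, reg$code)
  trait_model(reg$code, mu = reg$mean,
              sigma_g = sigma_g,
              sigma_ge = ge_prop * sigma_g,
              sigma_e = e_prop * sigma_g,
              season_sd = season_sd, rep_sd = rep_sd, block_sd = block_sd)
}

#' Simulated stand-in for the reference amaranth trial
#'
#' Generates a synthetic balanced trial with the structure of the reference
#' study: 120 genotypes, 2 seasons, 2 replicates per season, alpha-lattice
#' blocks of 15 plots, and all 24 traits of [amaranth_traits()]
#' (120 x 2 x 2 x 24 = 11,520 plot records). No field data ship with the
#' package; this fixture is synthetic.
#'
#' @param seed integer seed controlling both the layout randomization and
#'   the trait draws.
#' @return A list with elements `design`, `model` and `table` (the balanced
#'   `plot_table`).
#' @examples
#' \donttest{
#' fx <- amaranth_fixture(seed = 42)
#' nrow(fx$table)
#' }
#' @export
amaranth_fixture <- function(seed = 42) {
  seed <- as.integer(seed)
  design <- build_design(120, seasons = 2, reps = 2, block_size = 15,
                         seed = seed)
  model <- amaranth_model()
  table <- simulate_trial(design, model, seed = seed + 1L)
  list(design = design, model = model, table = table)
}
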