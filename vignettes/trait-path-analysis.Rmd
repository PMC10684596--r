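---
title: "Correlation and path-coefficient analysis for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation and path-coefficient analysis for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpath)
```

## The problem

Plant breeders rarely improve yield by selecting on yield alone: it is a
complex trait whose expression mixes many genetic and environmental causes.
Two statistical tools dominate the design of selection indices in crops:

* **genotypic vs phenotypic correlation** — splitting the observable
  association between two traits into its heritable part (driven by
  linkage and pleiotropy) and the part contributed by environment and
  measurement noise; and
* **path-coefficient analysis** (Dewey–Lu / Wright) — decomposing each
  predictor trait's correlation with yield into a *direct* effect and
  *indirect* effects routed through the other predictors, so the breeder
  can tell a genuine causal lever from a trait that merely hitchhikes.

`traitpath` implements this chain for balanced multi-environment trials —
the typical evaluation of a large genotype panel grown for two or more
seasons in a resolvable alpha-lattice with replicates — together with the
multicollinearity screen that must precede any path analysis, and a trial
simulator so the whole chain can be exercised and tested without field
data. The built-in fixture mirrors a 120-genotype amaranth panel measured
for 24 agro-morphological traits over 2 seasons × 2 replicates.

## The model

Every operation assumes the additive random model of a combined analysis
over environments. For genotype $g$, season $s$, replicate $r$ and a given
trait,

$$y_{gsr} = \mu + E_s + R_{r(s)} + B + G_g + (GE)_{gs} + \varepsilon_{gsr},$$

with genotype effects $G \sim \mathrm{MVN}(0, \Sigma_g)$ shared across
seasons, genotype-by-environment deviations
$(GE) \sim \mathrm{MVN}(0, \Sigma_{ge})$ redrawn per season, plot errors
$\varepsilon \sim \mathrm{MVN}(0, \Sigma_e)$, and scalar season/replicate/
incomplete-block nuisance effects. The covariance matrices are trait ×
trait, which is what makes *co*-variance components — and hence genotypic
correlations — estimable.

### Variance and covariance components

On a balanced table, the combined ANOVA strata (environment, replicate
within environment, genotype, genotype × environment, error) are
orthogonal, and the classical expected-mean-squares ladder applies:

$$E[\mathrm{MS}_e] = \sigma^2_e,\qquad
  E[\mathrm{MS}_{ge}] = \sigma^2_e + r\,\sigma^2_{ge},\qquad
  E[\mathrm{MS}_g] = \sigma^2_e + r\,\sigma^2_{ge} + rs\,\sigma^2_g.$$

`estimate_components()` solves this ladder by the method of moments for
each trait and, replacing squared deviations by cross-deviations
(`mean_cross_products()`), for each trait pair. Negative variance
estimates are clipped at zero and flagged — the standard convention —
while covariance components keep their sign. Phenotypic variance defaults
to the genotype-mean basis
$\sigma^2_p = \sigma^2_g + \sigma^2_{ge}/s + \sigma^2_e/(rs)$, matching
data that are analysed as genotype means over seasons and replicates; a
plot basis ($\sigma^2_g + \sigma^2_{ge} + \sigma^2_e$) is available via
`basis = "plot"`. A useful consequence of the mean basis is that the
phenotypic correlation it implies is algebraically identical to the plain
correlation of genotype means — a property the test suite asserts.

### Correlations and their significance

$$r_{p(xy)} = \frac{\mathrm{Cov}_{p}(x,y)}
    {\sqrt{\sigma^2_{p(x)}\,\sigma^2_{p(y)}}},\qquad
  r_{g(xy)} = \frac{\mathrm{Cov}_{g}(x,y)}
    {\sqrt{\sigma^2_{g(x)}\,\sigma^2_{g(y)}}}.$$

Because the genotypic quantities are ratios of noisy moment estimates,
$|r_g|$ can exceed 1. Such values are reported with an out-of-range flag
rather than clamped, so downstream arithmetic stays faithful to the
estimates (a `clamp = TRUE` option exists for numerical stability). A
genotypic variance clipped to zero makes $r_g$ undefined; the estimate
then carries the truncation reason instead of a number.

Both levels are tested two-sided against the tabulated critical $r$ at
$n-2$ degrees of freedom ($n$ = number of genotypes), with marks `*`,
`**`, `***` at the 5, 1 and 0.1 % levels. Using the same $n-2$ reference
for the genotypic level is a fidelity choice: the true sampling
distribution of $r_g$ is wider whenever heritability is low, so the marks
on $r_g$ should be read as conventional annotations, not exact tests. The
calibration check in the test suite therefore runs in a high-heritability
regime ($\sigma^2_{ge} = \sigma^2_e = 0.05\,\sigma^2_g$), where a variance
argument puts the expected size near 0.052; mild inflation (we observe
0.05–0.07) is inherent to the ratio estimator and documented rather than
corrected.

### Multicollinearity screen

Path coefficients come from inverting the predictor correlation matrix, so
near-collinear predictors produce wild, unstable coefficients. The screen
computes, per trait, the variance inflation factor
$\mathrm{VIF}_i = [R^{-1}]_{ii}$ and tolerance
$\mathrm{TOL}_i = 1/\mathrm{VIF}_i$, plus the eigenvalue condition number
$\mathrm{CN} = \lambda_{\max}/\lambda_{\min}$ banded as weak (< 100),
moderate (100–1000) or severe (> 1000). `screen_traits()` then removes the
worst non-protected trait (highest VIF, ties by list order) and recomputes
until every VIF is at or below the threshold (default 10, the conventional
cutoff; note that severe collinearity corresponds to TOL *below* 0.1).
Dependent yields are protected so the screen cannot delete the very traits
the paths are about. Removal is logged trait by trait, and the retained
set is re-audited.

### Path decomposition

With $R_{xx}$ the retained-predictor correlation matrix and $r_{xy}$ the
predictor–dependent correlations, the direct effects solve

$$P = R_{xx}^{-1}\, r_{xy},$$

identically the standardized partial-regression coefficients (the test
suite checks them against `lm()` on standardized genotype means to 1e-8).
Indirect effects are $r_{ik} P_k$, and the defining identity
$r_{iy} = P_i + \sum_{k \ne i} r_{ik} P_k$ is verified to 1e-10 on every
decomposition. The coefficient of determination is
$R^2 = \sum_i P_i r_{iy}$ and the residual factor
$\mathrm{RF} = \sqrt{1 - R^2}$ summarizes what the predictor set leaves
unexplained. Genotypic-level runs fed with out-of-range correlations can
produce $R^2 > 1$; the decomposition is then flagged over-determined and
RF withheld instead of being reported as a complex number.

Percent-contribution tables rescale each predictor row by its total
absolute effect, $100\,|e| / (|P_i| + \sum_{k\ne i} |r_{ik}P_k|)$, so every
row sums to 100. Published tables of this kind are often printed with the
rows labelled "indirect effect via X" actually listing X's indirect
effects *via the column traits*; our serialized tables state the
orientation explicitly in a header comment to avoid the ambiguity.

A condition-number guard (refuse $R_{xx}$ with CN > 10^6) replaces the
spreadsheet-style blind inversion sometimes used in this literature.

## The simulator and the amaranth fixture

`build_design()` lays out a resolvable alpha-lattice: every genotype once
per replicate, incomplete blocks of `block_size` plots, assignment
re-randomized per (season, replicate). `simulate_trial()` draws the model
above bit-reproducibly from a seed. Nuisance magnitudes are expressed as
multiples of each trait's genotypic SD because the traits carry different
units (a "0.5" season effect means half a genotypic SD for every trait).

`amaranth_fixture()` emulates the reference study's shape: 120 genotypes
× 2 seasons × 2 replicates × 24 traits (11,520 plot records, 8 blocks of
15 plots per replicate; the layout description "2 replications, 16
blocks, 15 plots per block" is ambiguous for 120 genotypes — we read it
as 8 blocks per replicate, 16 in total per season). Its genotypic
correlation matrix is assembled in two layers:

1. a hand-set 16-trait pattern encoding the study's strong relations
   (leaf-size cluster LW–LL–LA, inflorescence cluster AIL–TILL–TISL,
   architecture/phenology cluster, and the tight GY–GSFR link at 0.9).
   Hand-set pairwise patterns are rarely positive semi-definite, so the
   matrix is spectrally repaired; because plain eigenvalue clipping
   leaves the matrix singular and distorts the headline pairs, the repair
   iterates clipping at a floor of 0.10 with restoration of eight anchor
   correlations, converging to a well-conditioned matrix that keeps
   r(LW, LL) = r(GY, GSFR) = 0.90 exactly;
2. eight deliberately collinear traits (TSW, GFP, BLBL, TLBL, SD, NN, PL,
   LT), each an even-weight combination of two or three positively
   inter-correlated partner traits scaled to a multiple $R^2$ of 0.95
   (population VIF 20). The even spread matters: it keeps the partners'
   own VIFs near 14 or less at every step of the screen, so the
   constructed traits — not their partners — are the ones removed.

$\Sigma_{ge} = 0.25\,\Sigma_g$ and $\Sigma_e = 0.5\,\Sigma_g$ give a
plot-level heritability of 0.57 and a genotype-mean heritability of 0.8 —
typical for such panels — and make the mean-basis phenotypic correlation
matrix equal the configured genotypic one, which is convenient for
checking both estimators against a single target.

What the fixture does *not* emulate: spatial field trend, lattice
efficiency adjustments, per-plant subsampling (plot means only),
non-normal trait distributions, and unbalanced data. Tests passing on the
fixture therefore certify the estimators under the model's own
assumptions, not robustness to real-world messiness.

## Worked example

```{r}
bundle <- run_pipeline(amaranth_config(seed = 42))
bundle
```

The screen drops the eight constructed collinear traits (at the
occasional seed, sampling noise pushes a ninth trait's VIF just over 10 —
the threshold rule is applied as stated, so it too is removed and logged):

```{r}
bundle$screen
```

Each dependent is decomposed on 14 predictors (16 retained − itself − one
configured exclusion: GSFR is excluded from the leaf-yield paths and DM
from the grain-yield paths, mirroring the per-analysis exclusions of the
reference study):

```{r}
bundle$paths$GY.phenotypic
```

`write_report(bundle, dir)` serializes the correlation matrices (stars
appended), the screen log, one TSV per decomposition (4-decimal rounding
applied only at write time) and a provenance block, and returns the file
manifest.

## Numerical choices and edge cases

* **Blocks.** The EMS ladder ignores incomplete blocks by default (the
  randomized-complete-block approximation, appropriate because no lattice
  adjustment is defined for the covariance ladder); `blocks = "absorb"`
  removes the block-within-replicate stratum by sequential least squares
  before the genotype sum of squares, with cross-products recovered by
  polarization, $SCP = [SS(x+y) - SS(x) - SS(y)]/2$.
* **Missing plots** are a hard error listing the offending cells; the
  estimators are only valid on balanced data.
* **Truncation.** Negative $\hat\sigma^2$ are clipped with flags;
  covariances never are. A clipped genotypic variance propagates as an
  undefined $r_g$ with its reason, not as a silent `NA`.
* **Ties** in the screen resolve by trait-list order, compared with a
  relative tolerance of 1e-10 so that floating-point noise cannot flip
  the choice.
* **Determinism.** Design, simulation and pipeline are pure functions of
  their seeds; serialized reports are byte-identical across reruns.
* **Problem sizes in the test suite** were chosen for statistical
  resolution: correlation recovery at $G = 500$ (sampling s.e. ≈ 0.016
  for $r_g = 0.8$), variance-component recovery as a mean over 50 trials
  at $G = 300$ (relative s.e. ≈ 1.4 %), and test-size calibration over
  100 null trials of 6 trait pairs (99 % binomial band ≈ ±0.023 around
  0.05).

## Limitations

REML/mixed-model estimation, unbalanced-data EMS coefficients,
heritability reporting, standard errors for genotypic correlations and
path coefficients, and second-order path models are out of scope. The
significance marks on genotypic correlations inherit the $n-2$ convention
of the applied literature and should not be over-read when heritability
is low.
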