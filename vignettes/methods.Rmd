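---
title: "Non-linear Mendelian randomisation from stratified summarised data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataMR)
```

## The problem

Mendelian randomisation (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure $X$ on an outcome
$Y$. Standard summary-data MR assumes that effect is a single slope. When
the causal relationship $h(x)$ may be non-linear, semiparametric stratified
methods estimate the *local* slope of $h$ at different exposure levels —
but published implementations of those methods need the full
individual-level dataset, which often cannot be shared.

`strataMR` splits the analysis into two stages that can be run by
different analysts:

1. **Stage one** (needs individual-level data): stratify the sample and
   summarise each stratum by its genetic association with the exposure
   ($\hat\beta_{X,k}$, SE) and with the outcome ($\hat\beta_{Y,k}$, SE),
   plus the mean and percentile range of the exposure.
2. **Stage two** (needs only those summaries): estimate $h$ and its
   uncertainty.

Any file in the stage-one output format can be analysed, whatever
regression produced it — linear, logistic, or externally computed Cox
coefficients — because the modelling choices specific to the outcome type
are entirely contained in stage one.

## Stage one: residual-exposure stratification

Stratifying directly on $X$ would condition on a collider: $X$ is caused
by the instrument $G$, so strata of $X$ have distorted instrument
distributions. Instead we stratify on the *residual exposure*
$R = X - \mathbb{E}[X \mid G]$, estimated by OLS of $X$ on $G$ (intercept
included). $R$ is uncorrelated with $G$ by construction, so the instrument
distribution is (asymptotically) the same in every stratum.

Design choices, fixed and documented because downstream numbers depend on
them:

* **Residual regression covariates.** The residual is defined against the
  instrument only; covariates enter the within-stratum association
  regressions, not the residualisation (a flag enables the alternative as
  a sensitivity analysis). The definition of the residual exposure names
  only the genetic variants; which convention the original software uses
  is not documented, so the plain definition was taken.
* **Strata.** Equal-size quantile groups (default $K = 10$, deciles),
  ranked by residual with ties broken stably by input order; sizes differ
  by at most one, larger groups first. Requests with $K > n/2$ are
  refused.
* **Percentiles.** Within-stratum exposure range is reported as the
  10th/90th percentiles (20th/80th in the two extreme strata, to limit
  extrapolation), computed with the type-7 linear-interpolation quantile
  convention. The published description does not state a quantile
  algorithm; type 7 is R's default and is frozen here.
* **Missing data.** Complete-case on the used columns, with a logged
  count. The source description is silent on missingness.
* **Binary outcomes.** Unconditional maximum-likelihood logistic
  regression per stratum, same covariate set as the continuous case, no
  rare-event correction; $\hat\beta_{Y,k}$ is a log odds ratio per score
  unit.

## Stage two: LACE and the two curve estimators

The **localised average causal effect** in stratum $k$ is the ratio
$\widehat{\mathrm{LACE}}_k = \hat\beta_{Y,k} / \hat\beta_{X,k}$, valid
under the homogeneity assumption that the instrument-exposure effect is
constant across strata. Its standard error is the first-order
approximation $\mathrm{se}(\hat\beta_{Y,k}) / |\hat\beta_{X,k}|$; the
published text does not print an SE formula, and this is the standard
ratio-IV convention. A second-order delta option
($\sqrt{\mathrm{se}_Y^2/\beta_X^2 + \beta_Y^2 \mathrm{se}_X^2/\beta_X^4}$)
is available behind `se_method = "delta2"` and is never smaller.

Homogeneity itself is diagnosed on the $\hat\beta_{X,k}$ column with
Cochran's $Q$ (fixed-effect inverse-variance weights, $\chi^2_{K-1}$) and
a known-variance weighted meta-regression trend test (normal reference,
not $t$; the variances are treated as known, as in conventional
meta-analysis).

### Fractional polynomials

$h$ is modelled as a fractional polynomial with powers from
$P = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ ($p = 0$ meaning $\ln x$; a
repeated degree-2 power contributing $x^p \ln x$). The named shapes of the
method's description — linear, quadratic, cubic, logarithmic, reciprocal,
square-root — are the subset $\{1, 2, 3, 0, -1, 0.5\}$; the full standard
set is the default and can be restricted via `powers=`.

Because each LACE estimate is the local slope of $h$ at the stratum mean
$\bar x_k$, the fit is an inverse-variance weighted meta-regression of
$\widehat{\mathrm{LACE}}_k$ on the *derivative* basis
$\frac{d}{dx} x^p \big|_{\bar x_k}$, with **no intercept**: the level of
$h$ is not identified (only its shape), so the curve is anchored to zero at
a reference value $x_{\mathrm{ref}}$. With the derivative
parameterisation, the meta-regression coefficient of a term equals the
coefficient of that term in $h$ itself, so a single coefficient vector
describes both the fitted slopes and the integrated curve.

Model selection maximises the weighted normal log-likelihood
$-\tfrac12 \sum_k \left[ (r_k/\mathrm{se}_k)^2 +
\ln(2\pi\,\mathrm{se}_k^2) \right]$ over all $|P| = 8$ degree-1 models or
all $\binom{|P|+1}{2} = 36$ unordered degree-2 pairs with repetition.
Ties (exactly equal likelihoods) are broken toward smaller powers by
enumerating candidates in increasing order and requiring a strict
improvement. Exposures must be positive for non-integer powers; the CLI's
`--shift` adds and reports a constant.

Four non-linearity tests are reported: `fp_d1_d2` (LR of best degree 2
vs best degree 1), `fp` (LR of best degree 1 vs the linear model), `quad`
(trend in the LACE estimates), and `Q` (heterogeneity of the LACE
estimates). Both LR tests use a $\chi^2_1$ reference that **ignores the
power search**. This is a documented approximation (no df convention is
published): under a true linear model the best degree-1 fit is at least as
likely as the linear fit by construction, `p_fp` has an atom at 1 whenever
the linear model itself wins the search, and small `p_fp` values are
mildly over-represented. Consequently `p_fp` is *not* uniformly
distributed under the null — the null-calibration test in the acceptance
suite demonstrates this honestly (its `p_quad` and `p_q` components pass a
KS uniformity check; `p_fp` fails by construction).

### Piecewise linear curve

The continuous piecewise-linear estimate gives segment $k$ the slope
$\widehat{\mathrm{LACE}}_k$ over stratum $k$'s exposure range. Adjacent
reported ranges usually overlap (stratum $k$'s 90th percentile exceeds
stratum $k+1$'s 10th), and the original software's exact joining rule is
not described; here interior knots are placed at the midpoint of
$(\mathrm{upper}_k, \mathrm{lower}_{k+1})$, so the curve lives on the
connected interval $[\mathrm{lower}_1, \mathrm{upper}_K]$. Evaluation
outside that interval is an error — the stratified method deliberately
does not extrapolate. The reference value defaults to the
stratum-size-weighted mean of the stratum mean exposures (the overall
exposure mean is only available with individual-level data); the anchor
$h(x_{\mathrm{ref}}) = 0$ holds exactly in floating point because the
reference offset is computed through the same expression used for
evaluation.

## Uncertainty: two bootstraps

The **parametric bootstrap** (the summarised-data method) redraws
$\mathrm{LACE}^*_k \sim N(\widehat{\mathrm{LACE}}_k, \mathrm{se}_k)$
independently, refits the selected model with its powers held fixed, and
reports percentile intervals (coefficients and pointwise curve bands).
Powers are *not* re-selected per draw by default — selection uncertainty
is excluded, the published description being silent — with `reselect =
TRUE` as a sensitivity flag. All draws flow from one explicit seed that is
recorded in every output.

The **nonparametric bootstrap over individuals** is provided as a test
oracle for equivalence experiments, not as an analysis path. By default it
holds the original stratification fixed and resamples individuals within
their stratum, so the two bootstrap flavours are compared under identical
stratification — the comparison the equivalence experiments require.
Fully redoing residualisation and stratification inside each resample
(`restratify = TRUE`) is also implemented; it adds stratification noise
and heavy-tailed ratio draws in the extreme strata (where
$\hat\beta^*_{X,k}$ can approach zero), inflating the coefficient SE by
roughly 40% on the default synthetic data, which is why it is not the
default comparison.

### A known coverage limitation

The parametric bootstrap draws the per-stratum LACE estimates
independently. In truth they are slightly positively correlated (the
confounder ties the stratification variable to the outcome), so the
bootstrap SE of the pooled linear coefficient is a little too small. On
the default synthetic world (below) a 1000-replicate experiment measured
an empirical coefficient SD of 0.126 against a mean bootstrap SE of 0.110,
giving ~91% coverage for a nominal 95% interval. This is a property of the
published method's independence assumption, inherited deliberately; the
acceptance suite's coverage criterion (band 91–99% at 200 replicates)
sits exactly at this edge and is allowed to fail rather than being widened.

## The synthetic world

`sim_scenario()` / `generate_mr_data()` define the package's test bed,
mirroring the classic stratified-IV simulation structure:

* $G \sim \mathrm{Binomial}(2, 0.3)$ — a biallelic score with allele
  frequency 0.3;
* $U \sim N(0,1)$ — unobserved confounder;
* $X = c_0 + \alpha G + U + \varepsilon_X$, with $\alpha = 0.25$,
  $\varepsilon_X \sim N(0, 1)$ and $c_0 = 10$;
* continuous $Y = h(X) + U + \varepsilon_Y$, or binary
  $Y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(b_0 + h(X) + U))$.

$c_0 = 10$ keeps the exposure strictly positive (required by fractional
powers) with overwhelming margin at every sample size used; generation
errors out rather than silently shifting if a non-positive exposure ever
occurs. Shapes and default effect sizes: linear $0.32x$ (the published
LDL-cholesterol linear coefficient, used as a recognisable anchor),
quadratic $0.1x^2$, square-root $2\sqrt{x}$, threshold
$0.5\,(x - 10)_+$, and null. These constants were chosen once, before any
test thresholds were computed, and are not revisited.

What a green test does and does not establish: the generator has a single
homogeneous instrument, Gaussian confounding of equal strength on exposure
and outcome, and no covariates, measurement error, coarsened exposures, or
selection effects. Agreement and calibration results on this world say
nothing about weak-instrument behaviour, pleiotropy, or the exposure
coarsening the method explicitly warns against.

Two derived facts about this world, measured once and frozen into tests:
the `fp` non-linearity test has power $\approx 0.51$ (MC SE 0.022) against
the default quadratic scenario at $n = 5000$ (the module test guards
$\geq 0.44$), and coverage behaves as described above.

## Numerical choices

* WLS systems are solved via normal equations with a reciprocal-condition
  guard (`rcond < 1e-12` raises a collinearity error, e.g. a degree-2
  pair on too-few strata).
* Percentile CIs use type-7 quantiles of the draws.
* Determinism: every random routine takes an explicit seed, saves and
  restores the global RNG state, and records the seed in its output; the
  same configuration and seed reproduce byte-identical JSON reports.
* The interchange CSV (`stratum,bx,bxse,by,byse,xmean,xmin,xmax`) is
  written with 17 significant digits so write/read round-trips preserve
  values to at least 12 significant digits.

## Known limitations

* The LR reference distributions ignore power-search selection (above).
* The LACE SE ignores instrument-association uncertainty by default
  (option provided).
* No random-effects meta-regression, Egger-style pleiotropy diagnostics,
  BCa/studentised bootstraps, or spline/smoothing variants.
* The published ten-stratum worked-example dataset is not redistributed
  here; `ldl_cad_example()` carries only the four strata printed in the
  source text, which is enough to check the LACE arithmetic but not to
  reproduce the published model selection (the corresponding acceptance
  test is left failing by design rather than faked).
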