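---
title: "Geostatistics of soil organic carbon in a gridded desert survey: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistics of soil organic carbon in a gridded desert survey: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socgeo)
```

## The problem

Gobi-type (gravel-paved) temperate deserts hold little soil organic carbon
(SOC), but they cover enormous areas, so even small per-area stocks matter for
regional carbon budgets. Quantifying them raises three coupled questions that
this package answers as one pipeline:

1. **How variable is SOC, and over what distances is it spatially
   structured?** — descriptive statistics, semivariogram analysis, ordinary
   kriging.
2. **How does apparent variability grow with the size of the area sampled,
   and how many samples does a survey of a given extent need?** — sub-area
   re-sampling, power-law scaling of the coefficient of variation (CV),
   sample-size planning.
3. **How much carbon is there?** — layer densities and area stocks with
   coarse-fragment correction.

The reference design is a 5 km × 8 km area sampled on a closed regular 500 m
lattice (11 × 17 = 187 locations) at four depth layers (0–10, 10–20, 20–30,
30–40 cm), i.e. 748 composite samples, each with SOC concentration (g kg⁻¹),
stone/sand/silt/clay contents (%) and bulk density (g cm⁻³). No field data
ship with the package; a seeded random-field simulator reproduces the
statistical structure of such a survey so that every stage of the analysis is
testable end to end.

## The synthetic survey generator

`simulate_layer()` draws SOC for one depth layer as a log-normal random field

$$\mathrm{SOC}(\mathbf{x}) = \exp\!\Big(\mu + \beta\,(y - \bar y) +
\sigma\big[\sqrt{1-\nu}\,S(\mathbf{x}) + \sqrt{\nu}\,\varepsilon(\mathbf{x})\big]\Big),$$

where $S$ is a zero-mean, unit-variance Gaussian field with exponential
correlation $\exp(-3h/A)$, $\varepsilon$ is unit white noise,
$\nu \in [0,1]$ is the nugget ratio, $A$ the effective range in metres,
$\beta$ an optional south→north trend on the log scale (default 0), and
$(\mu, \sigma)$ are moment-matched so the *arithmetic* marginal mean and CV
equal the configured values exactly: $\sigma^2 = \log(1+c^2)$,
$\mu = \log(m) - \sigma^2/2$ (`lognormal_params()`). The field is generated
by exact Cholesky factorization of the 187 × 187 node covariance — exact and
essentially free at survey scale, which is why no spectral or turning-bands
approximation is used.

Two conventions deserve emphasis because software differs on both:

* **Effective range.** The configured $A$ is the distance at which
  correlation has decayed to ≈ 5% ($e^{-3}$). The variogram-fitting code uses
  the same convention, so generation → estimation → fitting is
  self-consistent; the raw exponential parameter ($A/3$) is stored alongside.
* **Log-scale sill.** By default the log-scale variance is derived from the
  marginal CV. It can instead be fixed directly (`sill_ln`), which is how a
  fitted variogram's sill is fed back into the generator for recovery
  experiments; the marginal mean is preserved either way.

Default per-layer parameters are the package's reference desert-survey
conditions: layer means 1.6/1.5/1.4/1.4 g kg⁻¹ with CVs 36.8–42.1%, nugget
ratios 0.018–0.054, effective ranges 1047–1347 m, and covariates (stones,
sand, silt, clay, bulk density) with the marginal means/CVs and SOC
correlations characteristic of a stone-rich desert profile (e.g. sand
r ≈ −0.68, silt r ≈ +0.68 in the surface layer).

**Covariates** are unit-Gaussian blends of the structural field $S$ with
independent noise. The blend weight is calibrated for log-normal attenuation:
the correlation between a Gaussian blend and $\exp$ of the log-field is
damped by $\sqrt{1-\nu}\,\sigma/\sqrt{e^{\sigma^2}-1}$, so the weight is the
target correlation divided by that factor (clamped to ±0.99). This makes the
*achieved raw-scale* Pearson correlations match their targets to within
±0.05 when averaged over seeds. Covariates are then mapped affinely to their
marginal mean and CV and clipped to physical ranges (percentages to [0, 100],
bulk density positive, texture triples rescaled when they sum past 100%).
Clipping is a deliberate simplification: at the high CVs of stones, silt and
clay (84–123%) a clipped Gaussian truncates 10–16% of draws, which distorts
those marginals noticeably; the clip fraction is therefore attached to every
simulated table and reported with a message when it exceeds 1%. What the
generator does *not* emulate: cross-layer correlation of SOC, anisotropy,
within-location compositing error (absorbed into the nugget), and the
boundedness of real texture data beyond simple clipping — so passing
recovery tests demonstrate estimator correctness under the stated model, not
robustness to every feature of real surveys.

## Descriptive statistics

`summarize_layer()` reports min/max/mean/median, SD ($n-1$), CV in percent,
and the small-sample-adjusted (type-2) skewness and excess kurtosis — the
convention of mainstream statistics packages. Normality is tested with the
plain one-sample Kolmogorov–Smirnov test against a normal with estimated
mean and SD, with the p-value from the asymptotic Kolmogorov distribution.
With estimated parameters this test is anticonservative (the Lilliefors
issue); it is implemented this way deliberately, for fidelity with common
survey practice, and `ks_normality(..., lilliefors = TRUE)` offers the
corrected test. The log-transform rule used downstream is: analyse
$\ln$ SOC when the raw-scale K-S test rejects at 0.05 but the log-scale test
does not — the standard remedy for the positive skew of SOC data.

Layer means are compared by one-way ANOVA with LSD (least significant
difference) mean separation: pairwise t-tests on the pooled MSE, letters
assigned by the insert-and-absorb compact-letter-display algorithm with
means sorted descending. LSD makes no familywise correction; that liberality
is part of the method being reproduced, not an oversight.

## CV–area scaling and sample-size planning

A $w \times h$ km sub-rectangle of the $W \times H$ km area (integer sides)
is a *re-sampling method*; all $W \cdot H$ methods collapse by area into
distinct re-sampling areas (40 methods → 24 areas for 5 × 8 km). Every
placement of every same-area method contributes one CV of the enclosed SOC
values, and placements are pooled with equal weight (`cv_area_curve()`).
Sub-area boundaries are *closed*, consistent with the closed 187-point
lattice, so boundary points belong to every adjacent placement; points are
never split or weighted. At the full area the curve equals the whole-sample
CV exactly.

The curve is summarized by ordinary least squares of $\log \mathrm{CV}$ on
$\log \mathrm{area}$: $\mathrm{CV} = a\,\mathrm{area}^{\,b}$, with $a$ the
CV at 1 km² and $b$ the scaling exponent. Sample-size planning inverts the
classical accuracy formula, $n = \lceil (z_{1-\alpha/2}\,\mathrm{CV}/\Delta)^2
\rceil$, with the normal quantile rather than a finite-df t (the sample size
is unknown a priori) and ceiling rounding because the result is a minimum.
With a surface-layer anchor of CV(1 km²) = 26.7% and $b = 0.0789$, the
planner returns 110, 227 and 326 samples for 1, 100 and 1000 km² at
Δ = 5%, 95% confidence.

## Semivariograms, model fitting, kriging

The empirical semivariogram is the method-of-moments estimator
$\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2$ over pairs binned by
separation. Defaults: 500-m half-open distance classes $((k-1)w, kw]$ kept
while $kw \le$ 4700 m — i.e. nine classes reaching 4500 m (the few pairs
between 4500 and 4700 m fall in no complete class and are excluded; this is
the reading of "nine 500-m intervals to 4700 m" adopted throughout). The
analysis scale defaults to $\ln$ SOC per the transform rule above; sills of
order 0.10–0.15 are only plausible on that scale. Directional estimates
(`direction`, `tol_deg`) support anisotropy diagnostics; a 90° tolerance
reproduces the omnidirectional estimate.

Four model families are available (exponential, spherical, Gaussian, linear),
all parameterized by nugget $C_0$, partial sill $C$ and *effective* range
$A$. Fitting is weighted least squares with pair-count weights $N(h)$ (the
common software default; Cressie's $N(h)/\gamma^2$ is an option). Because
each family is linear in $(C_0, C)$ given $A$, the fit profiles $A$ over a
200-point log-spaced grid on $(0, 2 \cdot \text{max\_dist}]$ and refines the
best bracket by golden-section search, with non-negativity of $C_0$ and $C$
enforced by boundary fits — deterministic, global within the grid
resolution, and verified in tests against a dense grid-search oracle.
`select_variogram()` ranks families by lowest weighted RSS, then highest
$R^2$, then fewest parameters. The nugget ratio $C_0/(C_0+C)$ classifies
spatial dependence as strong (< 0.25), moderate (0.25–0.75, inclusive) or
weak (> 0.75).

Ordinary kriging solves the standard semivariance system with a Lagrange
multiplier; the neighbourhood is global (all samples) — exact at survey
scale and free of search-window artefacts. Predictions at sampled locations
are exact when $C_0 = 0$; weights sum to 1 to 10⁻⁸; kriging variances are
clamped at zero with a warning if round-off drives them negative; duplicate
locations are rejected rather than silently regularized. Cross-validation
(`loo_cv()`) is leave-one-out with replacement — each point predicted from
all the others — summarized by ME, RMSE and RMSSE. Under the generating
model the standardized errors have unit variance, so mean RMSSE near 1 is
the calibration check.

Maps (`krige_map()`) are predicted on cell centres. When the analysis ran on
the log scale the default back-transform is the lognormal-kriging correction
$\exp(\hat y + \sigma^2/2 - \mu_{\mathrm{Lagrange}})$, with the naive
$\exp(\hat y)$ and no transform as alternatives; because survey reports are
often silent on this point, the choice applied is recorded in every raster
object.

## Recovery experiments and problem sizes

Two seeded experiments tie the generator and the estimators together (they
are also what `scripts/acceptance.R` recomputes):

* **Variogram recovery.** 200 surface-layer fields are generated with a
  log-scale sill of 0.1048, nugget ratio 0.0019/0.1048 and effective range
  1347 m; each yields a nine-class empirical semivariogram, and the
  *seed-averaged* semivariogram is fitted by WLS. The averaged-curve design
  is deliberate: with only nine bins and a first lag already at ~0.67 of the
  sill, the per-realization range estimate is weakly identified and
  right-skewed — a non-negligible fraction of single fits run to the
  optimizer's range bound, making their mean an artefact of that bound
  rather than of the field (in our runs the per-seed mean is ~2 700 m with a
  median of ~1 490 m). Averaging the empirical curves first is the standard
  way to check estimator calibration, and recovers the effective range to
  within a few percent. The per-realization *nugget ratio* is far better
  behaved; its plain mean stays below 0.25 ("strong" dependence) and is
  asserted per-seed.
* **Marginal calibration.** 500 surface-layer fields at mean 1.6 g kg⁻¹ and
  CV 36.8% give a mean sample CV within 2 percentage points of the target
  (spatial correlation biases a single realization's CV slightly downward;
  at these ranges the effect is a few tenths of a point).

These sizes (200 and 500 replicates on the 187-node lattice, plus a
100-replicate leave-one-out calibration on a 49-node lattice) were chosen so
the Monte-Carlo standard error is well inside each tolerance while the whole
suite runs in well under a minute.

## Stocks

Layer density is $\mathrm{SOCD} = 0.01\,\mathrm{SOC}\cdot\mathrm{BD}\cdot d
\,(1 - \mathrm{CF}/100)$ in kg C m⁻² (g kg⁻¹ × g cm⁻³ × cm), cumulated over
layers for profile density and multiplied by area for stocks. The
coarse-fragment flag defaults to on, but `soc_stocks()` always reports both
settings: in stony desert soils the correction changes densities
several-fold, and published per-layer densities are frequently consistent
only with the uncorrected arithmetic (bulk density already referring to the
fine-earth fraction is a common, usually unstated, convention). Per-location
densities are computed first and then averaged; a means-only mode supports
worked examples from published layer means. No extrapolation below the
deepest sampled layer is attempted.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/read → describe → scaling → variogram →
kriging → cross-validation → relationships → stocks from a single
configuration object (`run_config()`, YAML-serializable — YAML was chosen as
the config format because it is human-diffable and round-trips R lists
losslessly). One master seed drives everything; the simulator derives one
substream per layer, and all later stages are deterministic given the data,
so identical configuration + seed gives an identical report (fingerprinted
with a small FNV-1a hash). A failing stage is recorded with its message and
its dependents are skipped rather than crashing the run. Artifacts are plain
text: CSV tables, a JSON report, ESRI ASCII rasters.

## Known limitations

* The K-S normality test with estimated parameters is anticonservative
  unless the Lilliefors option is chosen.
* Stepwise selection (forward with backward elimination on partial-F
  p-values, defaults 0.05/0.10) inherits all the usual caveats of stepwise
  inference; explained-variance shares are sequential increments in entry
  order and depend on that order except for orthogonal predictors.
* Clipped-Gaussian covariates distort high-CV marginals (monitored, see
  above).
* No anisotropic model fitting (directional diagnostics only), no
  co-kriging, no conditional simulation, no projection/GIS support beyond
  the planar-metre frame.
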