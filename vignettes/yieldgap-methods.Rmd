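---
title: "Methods: boundary-line yield-gap analysis for orchard surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-line yield-gap analysis for orchard surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In perennial tree crops such as almond, the ceiling on kernel yield is set
by how much photosynthetically active radiation (PAR) the canopy intercepts:
a plot cannot out-yield its light capture. Observed yields, however, fall
below that ceiling to varying degrees, and the *shortfall* — the yield gap —
carries the signal of everything else: orchard age, winter and summer
weather, atmospheric dryness, radiation, and management. `yieldgap`
implements an analysis chain that separates the two questions:

1. **What is the attainable yield at a given light interception?**
   (boundary-line frontier estimation)
2. **What keeps plots below it?** (correlation screening, random forests,
   partial dependence, and decision-rule extraction on the normalized
   yield)

The package is organised around plot-year records: one row per experimental
plot per harvest year, carrying the orchard identity, location, cultivar,
age, spacing, measured light interception and kernel yield (lbs/acre).

## Light interception

Plot-level light interception (LI) is the canopy-intercepted PAR fraction

\[ \mathrm{fPAR} = 1 - \mathrm{PAR}_{below} / \mathrm{PAR}_{above}, \]

averaged over the sampled trees of the plot (`compute_fpar()`,
`aggregate_plot_li()`). LI is held internally as a fraction in [0, 1];
all bin labels and reports use percent. Below-canopy readings that exceed
the simultaneous above-canopy reading by up to 5% are treated as sensor
noise and clipped to fPAR = 0; larger excesses are rejected as inconsistent
measurements. No within-plot outlier filtering is applied before averaging.

## The yield-potential frontier

`li_frontier()` groups plot-years into half-open 5% LI bins, takes the
upper decile by yield within each bin (`ceiling(0.1 n)` members, ties
resolved by stable record order) as the local proxy for attainable yield,
averages LI and yield over that decile, and fits a zero-intercept line to
the bin means:

\[ \hat\beta = \frac{\sum_i x_i y_i}{\sum_i x_i^2}, \qquad
   y_p = \hat\beta \cdot \mathrm{LI}\,[\%]. \]

Design choices worth knowing:

* **Bins are equally weighted** in the regression, not weighted by member
  count: each bin mean is one observation of the frontier.
* **`min_bin_count = 20`** (so the decile holds at least two plots) keeps
  sparse extreme bins from leveraging the fit; they are flagged, not
  silently dropped.
* A **zero intercept** encodes the physical constraint that zero light
  capture supports zero yield.
* Per-cultivar frontiers are available via the `cultivar` filter, so a
  dominant cultivar can be analysed on its own stratum.

The normalized yield of a plot is \(y_n = y_o / y_p\) (`normalize_yield()`),
its shortfall from 1 being the yield-gap proxy. Values above 1 (plots that
beat the estimated frontier) are preserved, never clipped — they are
informative about frontier estimation error and occur for very few samples.

## Climate features

`build_feature_table()` turns monthly (PRISM-style) and daily
(Daymet-style) weather tables into one row per plot-year:

* monthly and seasonal means of precipitation, Tmax/Tmin/Tmean, VPDmax,
  SRAD and daylight duration, for the **current** and the **previous**
  year (`{var}_{period}_{cur|prev}`);
* monthly **extreme-hot-day counts** (`hotdays_m{MM}_{lag}`): days whose
  Tmax strictly exceeds the cell's 90th-percentile threshold for that
  calendar month, thresholds pooled over the reference decade
  (linear-interpolation quantile, per cell — a pooled-region variant would
  only require passing a merged cell);
* per-cell **long-term climatology** (`ltm_{var}_{period}`) at seasonal and
  annual scale.

Winter for year *Y* is Dec(*Y*−1) + Jan(*Y*) + Feb(*Y*): the
meteorological convention, and the one under which "a warm winter limits
the current crop" is well-defined. Orchards are joined to climate cells by
nearest coordinates (ties to the lowest cell id). Rows whose previous-year
climate is unavailable are dropped with a reported count rather than
imputed. Daylight duration is stored in hours.

## Model suite

**Screening.** `pearson_screen()` ranks candidate features by |Pearson r|
with the target and admits them greedily: a feature enters if |r| > 0.15
and its |r| with every already-admitted feature *of the same category*
(precipitation, temperature, VPD, radiation/daylength, extremes) stays
below 0.50. Both thresholds act on absolute correlations, so protective
and harmful associations are treated symmetrically. Cultivar is screened
as its integer code — an ordinal-arbitrary convenience that mirrors how a
single cultivar correlation row is usually reported; models themselves use
one-hot encoding.

**Forests.** `fit_rf()` wraps `ranger` with the classic regression-forest
defaults (500 trees, p/3 candidates per split, minimum node size 5),
single-threaded and seeded for reproducibility. `importance_incmse()`
reports %IncMSE — the increase in out-of-bag MSE when one predictor is
permuted, as a percentage of the baseline out-of-bag MSE. The default
engine uses the classic per-tree permutation computed during fitting (one
permutation draw per tree); a forest-level engine (`method =
"oob_forest"`, `n_repeats` permutations of the whole column) exists for
verification at small n, and the two agree on rankings.

**Partial dependence.** `partial_dependence()` averages model predictions
over background rows while sweeping one feature across an equally spaced
grid between its 1st and 99th percentiles (tails excluded to avoid
extrapolation artifacts; the grid policy is recorded on the result).

**Representative tree.** `fit_representative_tree()` fits CART regression
trees on bootstrap resamples, scores each on its out-of-bag rows, and
returns the best tree as an explicit rule set — the interpretable
counterpart to the forest.

**Scenarios.** For the overall-yield target, four feature sets are compared
under sixfold cross-validation (RMSE, R², RPIQ = IQR of the observations /
RMSE): **A** biological only (including LI), **B** biological + full
meteorological, **C** biological + screened meteorological, **D**
biological without LI + full meteorological. Fold assignment is a seeded
uniform shuffle at the plot-year level (an orchard-grouped mode would be a
natural extension; plot-year randomization is the default reported).
Rows are canonicalised by (plot_id, year) before the shuffle, so fold
membership — and every metric — is invariant to input row order. Fold
dispersion is reported as the standard deviation across folds, labelled as
such. The gap and LI interpretation models exclude LI from their own
predictors: the gap statistic already conditions on LI by construction,
and LI cannot explain itself.

The gap-model target is the normalized yield \(y_n\) itself rather than
\(1 - y_n\); the two are monotone images of each other and every direction
statement simply flips sign.

## The synthetic generator

Because multi-year orchard surveys of this kind are proprietary, the
package ships a generator (`simulate_dataset()`) whose defaults *are* the
study conditions the analysis assumes: 33 orchards on a 35.0–39.5 °N
gradient, 24 plots per orchard-year, survey years 2009–2018 (≈7,900
plot-years), and a true frontier slope of 57.9 lbs/acre per %LI.

* **Climate**: sinusoidal seasonal climatologies shifted by latitude
  (southern sites warmer, higher summer VPDmax), with interannual cell-year
  anomalies (winter Tmean sd ≈ 1.5 °C, summer VPDmax sd ≈ 3 hPa) that are
  deliberately comparable to the spatial gradient — otherwise long-term
  climatology columns act as pure latitude proxies and mask the causal
  seasonal variables. Tmin ≤ Tmean ≤ Tmax holds by construction; daily
  Tmax is centred on the monthly value; daylight duration follows the
  astronomical day length at each latitude. Climate starts two years
  before the survey so previous-year features exist for every survey year.
* **Light interception** saturates in age,
  \(LI = v \cdot 0.8 (1 - e^{-0.35\,\mathrm{age}})\), with a per-plot
  canopy-density multiplier \(v \sim U(0.70, 1.05)\), a small long-term
  spring-SRAD shift, Gaussian noise (sd 0.04), clipped to [0.05, 0.90].
* **Yield** is the potential \(57.9 \cdot LI\%\) times a gap multiplier
  \(g = u \cdot g_{age} \cdot g_{winter} \cdot g_{vpd} \cdot g_{srad}
  \cdot e^{\varepsilon}\), clipped to (0, 1.05]. The stress terms are
  hinges: a concave youth ramp vanishing at age 5 (maximum penalty 25% —
  yield losses concentrate in the youngest orchards), −10% per °C of
  winter Tmean above 10 °C, −4.5% per hPa of summer VPDmax above 40 hPa,
  and a mild April-SRAD benefit. \(u \sim U(0.65, 1)\) is an unmodelled
  management factor and \(\varepsilon \sim N(0, 0.12)\) a lognormal error —
  multiplicative because yield is nonnegative and its spread grows with
  LI. The cap at 1.05 leaves a small fraction (≈6%) of plots above the
  fitted frontier, matching the intended "very few beyond 1" structure.

The generator exposes every one of these numbers in `sim_config()`, and
`sim_truth` records the planted values so parameter-recovery tests can
compare estimates against ground truth. With `gap_effects = FALSE` and
`gap_noise_sd = 0` every yield sits exactly on the frontier — the
degenerate case used to test exact slope recovery.

**What the generator does not emulate**: spatially correlated weather
fields, soil and irrigation heterogeneity, bloom phenology and pollination
dynamics, carry-over (alternate-bearing) effects, and measurement error in
yield itself. Passing tests therefore demonstrate that the *pipeline*
recovers structure that is present; they do not certify the biological
model on real surveys.

## Numerical choices and problem sizes

* Quantiles everywhere (hot-day thresholds, PDP grid bounds, IQR) use the
  linear-interpolation empirical quantile; "upper 10-percentile" reads as
  the 90th percentile.
* Hot-day counting uses strict exceedance; a day exactly at the threshold
  is not hot.
* LI bin boundaries are half-open, `[k·w, (k+1)·w)`: a plot at exactly 15%
  belongs to [15, 20).
* Stage seeds are derived by hashing the master seed with the stage name
  (`derive_seed()`), so adding a stage never perturbs the randomness of
  existing ones, and results stay below 2³¹.
* The automated checks run cross-validation forests with 100 trees and
  interpretation forests with 200 trees on the default ≈7,900-plot survey;
  rankings and fold metrics are stable well below the 500-tree package
  default, which remains the default for interactive use. Partial
  dependence in the checks averages over a 1,000-row seeded background
  sample; the full-data average is the function default.

## Known limitations

* The frontier estimator is a point estimate; decile-selection uncertainty
  is not propagated (a bootstrap over plots is a straightforward
  extension and deliberately not bundled).
* The boundary line is strictly linear through the origin; saturating or
  quantile-regression frontiers are out of scope.
* Correlation screening is greedy and marginal: a feature whose effect is
  purely conditional can be missed, which is exactly why the forest
  scenarios also run with the *full* meteorological set.
* With near-collinear siblings (e.g. winter Tmean vs winter Tmax), which
  one the screen retains can flip between samples; the cross-correlation
  rule guarantees one of them survives, not which.
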