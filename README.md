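# yieldgap

Boundary-line yield-gap analysis for orchard light-interception surveys.

In almond and similar tree crops, canopy light interception (LI, the fPAR
fraction `1 − PAR_below / PAR_above`) sets the ceiling on kernel yield. This
package is for agronomists and crop-data scientists who have plot-year
survey records (LI, yield, orchard descriptors) plus gridded climate
products, and want to answer two questions:

1. **What yield is attainable at a given LI?** Plot-years are grouped into
   5% LI bins, the upper decile by yield within each bin proxies the local
   attainable yield, and a zero-intercept line is fitted to the bin means:

   `ŷ_p = β · LI[%]`, with `β = Σxᵢyᵢ / Σxᵢ²` — the yield-potential
   frontier (lbs/acre per LI percentage point).

2. **What holds plots below it?** The normalized yield `y_n = y_o / y_p`
   (its shortfall from 1 is the yield gap) is modelled against biological
   and climate features: Pearson screening (|r| > 0.15 with the target,
   within-category cross-|r| < 0.50), random forests with out-of-bag
   permutation importance (%IncMSE), partial-dependence curves, a
   representative CART rule set, and sixfold cross-validated comparison of
   four feature scenarios (RMSE, R², RPIQ = IQR/RMSE).

A deterministic synthetic generator (`simulate_dataset()`) reproduces the
survey structure end to end — multi-orchard latitudinal climate gradient,
age-saturating LI, a linear frontier with planted stress effects (winter
warmth above 10 °C, summer VPDmax above 40 hPa, orchard youth below age
5) — so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(yieldgap)
library(dplyr)

sim <- simulate_dataset(sim_config(seed = 42))   # ~7,900 plot-years
frontier <- li_frontier(sim$plots)
frontier
#> Light-interception yield-potential frontier (zero intercept)
#>   slope: 56.72 lbs/acre per LI percentage point
#>   R^2 (bin means): 0.9874 over 16 bins (width 5%)
```

The estimated slope (56.7) recovers the generator's true 57.9 within ~2%,
and the bin means are almost exactly collinear (R² 0.99): each extra
percentage point of light interception is worth ≈57 lbs/acre of potential
yield. Normalizing observed yields by the frontier gives the gap statistic:

```r
gaps <- compute_gaps(sim$plots, frontier)
head(gaps, 3)
#> # A tibble: 3 × 5
#>   plot_id        year   y_o   y_p   y_n
#> 1 O01_Y2009_P01  2009 1263. 4069. 0.310
#> 2 O01_Y2009_P02  2009 1137. 3431. 0.332
#> 3 O01_Y2009_P03  2009 1295. 2816. 0.460
mean(gaps$y_n > 1)   # 6.1% of plots sit (slightly) above the frontier
```

Screen climate features against the gap, fit the interpretation forest,
and extract the decision rules:

```r
ft <- build_feature_table(sim$plots, sim$monthly, sim$daily)
data <- inner_join(ft, gaps[c("plot_id", "year", "y_n")],
                   by = c("plot_id", "year"))
screen <- pearson_screen(data, "y_n", candidates = <meteorological columns>)
head(as_tibble(screen), 2)
#>   feature           category      r p_value selected reason
#> 1 vpdmax_summer_cur vpd      -0.540       0 TRUE     selected
#> 2 vpdmax_m06_cur    vpd      -0.524       0 FALSE    redundant within category

fit <- fit_rf(data, "y_n", c(bio_without_li, selected_features(screen)),
              num.trees = 200, seed = 1)
head(importance_incmse(fit), 3)
#>   feature           inc_mse_pct  rank
#> 1 vpdmax_summer_cur       66.4      1
#> 2 tmean_winter_cur        58.0      2
#> 3 age                     21.2      3

fit_representative_tree(data, "y_n", <same features>, seed = 1)
#> Representative regression tree (candidate 3 of 25, OOB RMSE 0.1286)
#>   ...
#>   [n= 608, mean=0.693] tmean_winter_cur < 10.98 & vpdmax_summer_cur < 42.03 & age < 4.5
#>   [n=3390, mean=0.828] tmean_winter_cur < 10.98 & vpdmax_summer_cur < 42.03 & age >= 4.5
```

The forest ranks summer VPDmax, winter mean temperature and tree age as the
top gap drivers, and the best bootstrap tree recovers the planted
thresholds: cool-winter (<11 °C), low-VPD (<42 hPa), mature (age ≥ 5) plots
average a normalized yield of 0.83, versus 0.33 for warm-winter/high-VPD
plots — the generator's planted 10 °C and 40 hPa hinges, found from data.

`cross_validate()` / `run_scenarios()` compare the yield-model scenarios
(A biological incl. LI; B + full meteorology; C + screened meteorology;
D without LI), and `run_all(run_config(...), out_dir)` executes the whole
chain — simulate (or load CSVs), features, frontier, gaps, screening,
forests, rules — writing CSV/JSON artifacts plus an md5 manifest; results
are byte-identical under a fixed master seed. A command-line wrapper lives
in `inst/cli/yieldgap.R`.

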