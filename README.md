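# borealfire

Statistical tools for linking boreal forest fire history to ocean and
climate variability.  The package is aimed at fire-history and
paleoclimate analysts working with multi-site fire records
(dendrochronological fire scars, forestry statistics, sediment
charcoal) alongside temperature/SST/sea-ice proxy series and gridded
climate fields, who need the full inferential chain in one tested,
seeded, scriptable place:

* **Large fire year (LFY) detection.**  A year's burn count among `N`
  recording areas is referred to the binomial null
  `P(X) = C(N, X) p^X q^(N-X)`, `q = 1 - p`, with `p` pooled from the
  record; years in the extreme upper tail (optionally also passing a
  synchronicity floor) are flagged, and the record-wide fit is
  summarized by a Pearson chi-square test on the burn-count
  frequencies.
* **Regime shift detection.**  Sequential t-tests with the Regime
  Shift Index: `RSI = sum_m x*_(c+m) / (l sigma_l)`, where `l` is the
  regime cut-off length, `sigma_l` the pooled window standard
  deviation, and `x*` the Huber-weighted deviation beyond the
  significant level `mean +- t sqrt(2 sigma_l^2 / l)`.  Includes OLS
  red-noise estimation with bias correction and prewhitening, and a
  CUSUM change-time localizer.
* **Cold-regime clustering.**  A bootstrap test of whether LFYs fall
  preferentially in cold regimes: the observed `cold - warm` count
  difference against 1000 resamples of random event years, with 95%
  interval and 99.9% quantile.
* **Teleconnection field statistics.**  Pearson correlation maps
  between a fire index and gridded monthly fields with
  autocorrelation-adjusted effective sample sizes
  (`n_eff = n (1 - r1 r1') / (1 + r1 r1')`), Monte-Carlo field
  significance, moving-window correlation stability, and superposed
  epoch analysis over event years.
* **Seeded synthetic data** for every input class (AR(1) proxies,
  regime series, site-burn matrices, teleconnected fields), so the
  whole chain runs and tests without any external dataset.

Everything is tibble-first: functions take data frames and return
tibbles or small result objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate a 500-year, 20-site fire record (1401-1900) with ten
high-synchrony fire years placed mostly in cold periods, then run the
chain:

```r
library(borealfire)

fire <- gen_site_burn_matrix(500, 20, base_p = 0.02,
                             lfy_years = c(30, 160, 185, 215, 240, 265,
                                           320, 420, 450, 480),
                             lfy_p = 0.4, seed = 11, start_year = 1401)
lfy <- detect_lfy(fire, alpha = 0.05)
glance(lfy)
#> # A tibble: 1 x 8
#>    p_hat n_years n_lfy alpha min_fraction chi_square_stat chi_square_df
#> 1 0.0248     500    13  0.05            0            31.0             2
```

The pooled burn probability is ~0.025; 13 years sit in the binomial
upper tail at alpha = 0.05 (the ten planted years plus a few flagged by
chance — about `500 * P[X >= 3]` is expected from multiplicity).  The
chi-square statistic rejects the plain binomial fit because the planted
years inflate the extreme count classes.  Per-year diagnostics:

```r
dplyr::filter(lfy, is_lfy) |> head(3)
#>    year     N     X fraction_burned    tail_prob is_lfy
#> 1  1430    20     8            0.4  0.0000000138 TRUE
#> 2  1488    20     3            0.15 0.0127       TRUE
#> 3  1560    20     8            0.4  0.0000000138 TRUE
```

Segment a synthetic summer-temperature reconstruction into regimes and
test whether the fire years cluster in the cold ones:

```r
temp <- gen_regime_series(
  data.frame(length = c(150, 120, 130, 100), mean = c(0, -0.8, 0.4, -0.6)),
  ar1 = 0.3, seed = 12, start_year = 1401, label = "summer temperature")
seg <- detect_regimes(detrend_linear(temp), cutoff_l = 100)
tidy(seg)
#> # A tibble: 8 x 6
#>   start   end     n   mean      rsi provisional
#> 1  1401  1544   144  0.197 NA       NA
#> 2  1545  1671   127 -0.637  0.440   FALSE
#> 3  1672  1797   126  0.628  0.465   FALSE
#> 4  1798  1892    95 -0.251  0.491   FALSE
#> ...
```

Three shifts are confirmed (close to the planted boundaries at 1551,
1671, 1801); the short trailing regimes are marked provisional because
their test windows run past the series end.  The clustering test:

```r
bt <- bootstrap_lfy_test(lfy$year[lfy$is_lfy], label_years(seg),
                         n_boot = 1000, seed = 13)
bt
#> # LFY cold/warm bootstrap: 9 cold vs 4 warm (diff 5);
#> #   null 95% CI [-7, 5], 99.9% quantile 11.002, one-sided p = 0.091
```

Nine of thirteen detected fire years fall in cold regimes; the
difference sits at the upper edge of the null's 95% interval.
`run_pipeline(default_pipeline_config(1))` chains the same stages plus
the teleconnection map and superposed epoch analysis, writing one CSV
per stage and a JSON-lines log of every seed and parameter;
`autoplot()` methods draw each result type.

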