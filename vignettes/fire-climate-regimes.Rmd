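---
title: "Methods: fire-climate regime statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-climate regime statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealfire)
```

`borealfire` implements the statistical chain used to relate boreal
forest fire activity to ocean/climate state: detection of *large fire
years* (LFYs) from multi-site fire records, regime shift detection on
fire and climate proxy series, a bootstrap test of LFY clustering in
cold regimes, and teleconnection statistics between a scalar fire index
and gridded monthly fields.  This vignette records the models, the
tunable parameters, and the numerical and design choices, so that every
default can be traced to a reason.

## Large fire years from a binomial null

A multi-site fire history gives, for each year, the number of recording
areas $N$ and the number that burned $X$.  Treating each area as an
independent Bernoulli trial with annual burn probability $p$, the
probability of observing exactly $X$ burned areas is

$$P(X) = \binom{N}{X} p^X q^{\,N-X}, \qquad q = 1 - p .$$

`binomial_pmf()` evaluates this in log space (stable to $N \sim 10^4$);
`estimate_p()` pools $p$ over the whole record (burned site-years over
recording site-years), with an optional year-range restriction for
period-specific estimates.  `detect_lfy()` flags a year as an LFY when
its upper-tail probability $P[\text{count} \ge X]$ is at most `alpha`
(default 0.05, one-sided: large years are excesses) *and* the fraction
of sites burned reaches `min_fraction`.  `min_fraction` defaults to 0
because published synchronicity thresholds vary between site networks;
it exists because a per-year tail test at level $\alpha$ over hundreds
of years will flag a handful of ordinary years by multiplicity alone
(about $n_\text{years}$ times the attained tail level), and a
synchronicity floor is the field's usual second condition.

The record-wide fit of the binomial null is summarized by a Pearson
chi-square test of the observed frequencies of yearly burn counts
against expectation (`chi_square_contingency()`).  Count classes are
pooled from the top until every expected count is at least 5 (Cochran's
rule); degrees of freedom are `classes - 1 - 1` when $p$ was estimated
from the same record.  When $N$ varies between years the expected class
probabilities are the mixture over the years' binomials.  Years with no
recording site are skipped entirely, not treated as $X = 0$.

## Regime shift detection (sequential t-tests, RSI)

`detect_regimes()` scans a series for step changes in the mean.  The
scale of the test is $\sigma_l$, computed by `sigma_l()` as the square
root of the *mean of sample variances* over every contiguous window of
the cut-off length $l$.  (Averaging variances rather than standard
deviations is the stable pooling convention; with the alternative the
thresholds change by well under 1% at these window lengths.)  Two
regimes of length $l$ differ detectably when their means differ by

$$\mathrm{diff} = t_{1-\alpha/2,\,2l-2} \sqrt{2\sigma_l^2 / l},$$

the two-sample $t$ threshold with $2l-2$ degrees of freedom
(`threshold_diff()`).  The scan maintains the current regime's
Huber-weighted mean (weight $\min(1, h/|z|)$ with $z$ the deviation in
$\sigma_l$ units; `huber_h = 1` by default, so outliers beyond one
scale unit have bounded influence).  While a regime is younger than $l$
points its mean uses the first $l$ points of the regime; afterwards it
grows with the regime.  Scanning starts after the initial $l$-point
window.

An observation beyond mean $\pm$ diff opens a candidate change point
$c$ with hypothetical new level $\bar x \pm \mathrm{diff}$.  Over the
following $l$ points the Regime Shift Index accumulates the
Huber-weighted normalized deviations beyond that level,
$\mathrm{RSI} = \sum_m x^*_{c+m} / (l\,\sigma_l)$; if the running sum
ever drops below zero the candidate is rejected (the value joins the
current regime) and scanning resumes; if it stays positive through the
full window the shift is confirmed.  A window truncated by the series
end yields a *provisional* shift, reported separately and excluded from
confirmed-shift counts.

**Change-time estimation.**  Because the trigger is a single
observation, a noise excursion a few steps before a true step can open
the surviving candidate, biasing the raw candidate index early.  After
confirmation the shift time is therefore re-estimated within the test
window by the classical localizer: iterated two-means segmentation,
i.e. the CUSUM argmin of deviations from the midpoint between the old
and the (Huber) new-regime level, iterated to convergence.  This leaves
the confirm/reject decision untouched (it is exactly the sequential
rule above, and is verified against a brute-force transcription in the
tests) and centres the estimated change year on the true step.

**Prewhitening.**  For autocorrelated series, `prewhiten_ar1()`
estimates the lag-1 coefficient by ordinary least squares on every
contiguous subsample of length `round(subsample_frac * cutoff_l)`
(default fraction 0.5), corrects each estimate for finite-sample bias
as $\hat a' = \hat a + (1 + 4\hat a)/m$, averages, and removes the red
noise as $y_t = x_t - \hat a x_{t-1}$.  Linear detrending
(`detrend_linear()`) is the caller's responsibility, applied before
regime detection of temperature/SST/ice series so that a long-term
trend is not segmented into staircase regimes.

Cut-off lengths follow the record resolution: 100 steps for annual
records, 800 years for coarse (multi-century) Holocene series; the
significance level defaults to 0.1.  Shorter cut-offs make the detector
more sensitive and more false-alarm prone.  One honest caveat measured
by the acceptance script: on a 500-point stationary noise series with
$l = 100$ and $\alpha = 0.1$, the chance that at least one spurious
shift is confirmed somewhere in the series is roughly a third — the
nominal $\alpha$ applies per candidate window, not per series.  Treat
single confirmed shifts in short noisy series with corresponding
caution.

## LFY clustering in cold regimes

`label_years()` inherits each year's label from its regime: cold when
the regime mean is below the overall series mean.  Labels therefore
shift-invariantly follow the segmentation, not an absolute threshold.
`bootstrap_lfy_test()` computes the observed difference
`count(cold) - count(warm)` over the event years and builds the null by
drawing the same number of years uniformly *with replacement* from all
labeled years (1000 draws by default), preserving regime durations; a
without-replacement permutation variant is available via
`replace = FALSE`.  The p-value is one-sided (cold excess), the
fraction of null differences at least as large as observed, and the
95% interval and 99.9% quantile of the null are reported.  Note the
statistic is integer-valued: with few events its null distribution is a
coarse lattice and attainable test sizes sit below the nominal level —
the reported p-value is exact-conservative, not anti-conservative.

## Teleconnection statistics on gridded fields

`seasonal_index()` averages a monthly field over a month window (e.g.
April-May) per year.  `correlation_map()` computes the Pearson
correlation of an index with every cell over the overlapping years.
Local significance uses a two-sided $t$ test with the effective sample
size

$$n_\mathrm{eff} = n\,\frac{1 - r_1 r_1'}{1 + r_1 r_1'},$$

where $r_1, r_1'$ are the lag-1 autocorrelations of the two series
(`effective_n()`, floored at 3 and capped at $n$; a negative product
would exceed $n$ and is capped).  Field significance is Monte-Carlo:
the fraction of locally significant cells is compared with `n_perm`
permutations of the index years, which preserves the field's spatial
correlation structure exactly; `p_field` is the fraction of
permutations with at least the observed significant fraction.  No area
weighting is applied to cell fractions (grids here are regular and the
statistic follows the plain-fraction convention).  Missing cells are
excluded from numerator and denominator.

`moving_correlation()` reports windowed correlations (default window
31 years, centred timestamps) for stability checks.  `sea()` performs
superposed epoch analysis: the composite anomaly over event years
(relative to the all-year climatology) per requested month, with
two-sided p-values from `n_boot` random draws of equally many years
without replacement.  With $k$ event years the composite noise scale is
$\approx \sigma\sqrt{1/k - 1/n}$; with the study-typical $k = 5$ a
1-sd anomaly is recovered in magnitude but flags roughly
three-quarters of affected cells at the 10% level — per-cell power is
limited by design, which is why SEA maps are read as coherent regions,
not cell lists.

## Synthetic data: what it emulates, and what not

The generators provide seeded, bit-reproducible inputs with the
statistical structure the analysis assumes:

* `gen_ar1_series()` — stationary AR(1) red noise; the first value is
  drawn from the stationary distribution so short series carry no
  burn-in transient; innovations are scaled so the *marginal* sd is the
  one requested.
* `gen_regime_series()` — AR(1) noise plus a piecewise-constant mean
  (contiguous segments).
* `gen_site_burn_matrix()` — independent site-year Bernoulli burns,
  probability `base_p` except in planted LFY years (`lfy_p`); all sites
  recording.  The study-scale configuration used throughout the tests
  is 500 years x 20 sites, `base_p = 0.02`, ten planted years at
  `lfy_p = 0.4`.
* `gen_teleconnected_field()` — unit white noise with a rectangular
  block carrying `coupling * z(index)` plus noise of sd `noise_sd`, so
  the in-block correlation is `coupling / sqrt(coupling^2 + noise_sd^2)`
  — a localized centre of action in a larger domain.

Real proxy data differ in ways the generators deliberately ignore: no
spatial covariance outside the planted block, no persistence in site
burning, no sediment age-model error, no tree-ring detrending
artefacts.  Passing tests therefore demonstrate the *statistical
machinery* under its own assumptions, not the field validity of any
reconstruction.

The demonstration pipeline (`run_pipeline()`,
`default_pipeline_config()`) chains everything at study scale: the ten
planted fire years are placed preferentially in the cold segments of
the synthetic temperature series, emulating the association the
analysis is designed to detect, and the modern 100-year fire index is
coupled (negatively, coupling -0.5) to a block of a 20 x 30 annual
field.  Every stage writes a CSV and logs its seed and parameters as
JSON lines; reruns with the same configuration are bit-identical.

## Numerical choices and degenerate inputs

* Canonical time is calendar year AD; series flagged as cal yr BP are
  converted on read as AD = 1950 - BP.
* Bins are left-closed, right-open, anchored at the earliest covered
  time (composites share the earliest time over all sites); empty bins
  are missing, and compositing averages over the sites with data per
  bin, reporting `n_sites` per bin.
* `moving_cumulative()` timestamps windows by their start year.
* Charcoal preparation shifts each site by 1% of its maximum before the
  Box-Cox transform so zero counts are admissible; the exponent is
  fitted per site by profile maximum likelihood on $[-2, 2]$ unless
  fixed.
* Constant series raise degenerate-input errors from `standardize()`;
  a constant regime-detection input returns a single regime; constant
  correlation windows yield missing values rather than errors.
* Huber mean iterations converge to $10^{-10}$; `huber_h = Inf`
  reduces every weighted mean to the ordinary mean (tested to
  $10^{-10}$).
* All Monte-Carlo machinery (bootstrap, permutations, SEA draws,
  generators) consumes explicit integer seeds and restores the
  caller's RNG state.

## Problem sizes in the shipped tests

The test suite exercises the chain at the sizes the methods are meant
for while staying desk-fast: LFY recovery and chi-square calibration on
500-year x 20-site records (up to 1000 replicates), step detection on
500-point series over 100-300 seeds, prewhitening at n = 5000,
teleconnection recovery on a 40 x 60 grid over 100 years with ~200-1000
permutations, SEA on 8 x 10 x 40 fields with 500-1000 draws, and the
full pipeline twice for bit-identity.  `scripts/acceptance.R`
recomputes the same operating characteristics from scratch at a chosen
seed.

## Known limitations

* The regime detector estimates mean shifts only (no variance or
  correlation shifts) and offers no automatic cut-off selection.
* Field significance and SEA assume complete (or consistently masked)
  grids; no regridding between products is provided.
* The bootstrap clustering test resamples years, not blocks, so it
  tests clustering against regime durations, not against temporal
  autocorrelation of events.
* No age-depth modelling or radiocarbon calibration: series enter on
  their published time axes.
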