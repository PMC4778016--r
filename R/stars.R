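#' Average standard deviation over windows of the cut-off length
#'
#' The scale parameter of the regime shift test: sample variances are
#' computed over every contiguous window of length `l`, averaged, and
#' square-rooted.  Pooling variances (rather than averaging standard
#' deviations) is the numerically stable convention.
#'
#' @param series Data frame with `time`, `value`, or a numeric vector.
#' @param l Window length (the regime cut-off length), `2 <= l <=`
#'   series length.
#' @return The pooled within-window standard deviation.
#' @export
sigma_l <- function(series, l) {
  x <- if (is.numeric(series)) series else as_proxy_series(series)$value
  l <- check_count(l, "l", lower = 2L)
  n <- length(x)
  if (l > n) stop_invalid("`l` exceeds the series length")
  # windowed variances via cumulative sums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - l + 1L)
  sums <- cs[i + l] - cs[i]
  sums2 <- cs2[i + l] - cs2[i]
  vars <- pmax((sums2 - sums^2 / l) / (l - 1), 0)
  sqrt(mean(vars))
}

#' Detection threshold of the sequential t-test
#'
#' The minimum mean difference between two adjacent regimes of length
#' `l` that a two-sample t-test at level `alpha` would call significant:
#' `t_crit * sqrt(2 * sigma_l^2 / l)` with `2l - 2` degrees of freedom.
#'
#' @param l Regime cut-off length.
#' @param alpha Two-sided significance level.
#' @param sigma_l Pooled within-window standard deviation (see
#'   [sigma_l()]).
#' @return The threshold difference in series units.
#' @export
threshold_diff <- function(l, alpha, sigma_l) {
  l <- check_count(l, "l", lower = 2L)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  check_number(sigma_l, "sigma_l", lower = 0)
  qt(1 - alpha / 2, df = 2 * l - 2) * sqrt(2 * sigma_l^2 / l)
}

#' Huber weight for outlier down-weighting
#'
#' Weight 1 for deviations within `h` scale units of the tentative
#' regime mean, and `h / |z|` beyond, so distant outliers contribute
#' with bounded influence to regime means and to the Regime Shift Index.
#'
#' @param z Deviation from the regime mean in `sigma_l` units
#'   (vectorized).
#' @param h Huber parameter, > 0 (1 in the standard configuration).
#' @return Weights in `(0, 1]`.
#' @export
huber_weight <- function(z, h = 1) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h)) {
    stop_invalid("`h` must be a single positive number")
  }
  if (h <= 0) stop_invalid("`h` must be > 0")
  az <- abs(z)
  ifelse(az <= h, 1, h / az)
}

# Huber-weighted mean: iteratively reweighted, deviations measured in
# `scale` units.  Warm start keeps the sequential scan cheap.
huber_mean <- function(x, scale, h, start = mean(x), tol = 1e-10,
                       max_iter = 100L) {
  if (!is.finite(scale) || scale <= 0 || is.infinite(h)) return(mean(x))
  mu <- start
  for (iter in seq_len(max_iter)) {
    w <- huber_weight((x - mu) / scale, h)
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol) return(mu_new)
    mu <- mu_new
  }
  mu
}

#' Estimate and remove lag-1 red noise
#'
#' Ordinary least-squares estimates of the lag-1 autoregressive
#' coefficient are computed on every contiguous subsample of length
#' `round(subsample_frac * cutoff_l)`, bias-corrected as
#' `a' = a + (1 + 4 a) / m` (inverse-proportionality correction for the
#' finite-sample OLS bias), and averaged.  The prewhitened series is
#' `y[t] = x[t] - a_hat * x[t-1]`.
#'
#' @param series Data frame with `time`, `value`, length >= 10.
#' @param cutoff_l Regime cut-off length the estimate is tied to.
#' @param subsample_frac Subsample length as a fraction of `cutoff_l`
#'   (default 0.5).
#' @return List with `series` (the prewhitened [proxy_series()], one
#'   point shorter) and `ar1_hat` (the averaged corrected estimate).
#' @export
prewhiten_ar1 <- function(series, cutoff_l = 100, subsample_frac = 0.5) {
  series <- as_proxy_series(series)
  x <- series$value
  n <- length(x)
  if (n < 10L) stop_degenerate("series too short to prewhiten (need >= 10)")
  check_number(subsample_frac, "subsample_frac")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop_invalid("`subsample_frac` must be in (0, 1]")
  }
  m <- max(5L, round(subsample_frac * cutoff_l))
  m <- min(m, n)
  starts <- seq_len(n - m + 1L)
  ests <- vapply(starts, function(s) {
    xs <- x[s:(s + m - 1L)]
    x0 <- xs[-m]
    x1 <- xs[-1]
    denom <- sum((x0 - mean(x0))^2)
    if (denom == 0) return(NA_real_)
    a <- sum((x0 - mean(x0)) * (x1 - mean(x1))) / denom
    a + (1 + 4 * a) / m              # finite-sample bias correction
  }, numeric(1))
  a_hat <- mean(ests, na.rm = TRUE)
  a_hat <- max(min(a_hat, 0.99), -0.99)
  out <- proxy_series(series$time[-1], x[-1] - a_hat * x[-n],
                      resolution = series_resolution(series),
                      label = paste0("prewhitened ", series_label(series)))
  list(series = out, ar1_hat = a_hat)
}

#' Detect regime shifts by sequential t-tests (Regime Shift Index)
#'
#' Sequential scan of a series for step changes in the mean.  A current
#' regime mean (Huber-weighted) is maintained; an observation deviating
#' from it by more than the [threshold_diff()] opens a candidate change
#' point `c` with a hypothetical new-regime level at `mean +/- diff`.
#' Over the following test window of `cutoff_l` points the Regime Shift
#' Index accumulates the Huber-weighted normalized deviations beyond the
#' hypothetical level,
#' `RSI = sum(x_i^*) / (l * sigma_l)`; if the running sum ever drops
#' below zero the candidate is rejected and scanning resumes, while an
#' RSI that stays positive through the full window confirms the shift
#' and a new regime is opened.  Because single-point triggering can fire
#' a few steps before the true change when noise runs high, the time of
#' a confirmed shift is estimated within the test window by the
#' standard change-point localizer: iterated two-means segmentation
#' (CUSUM argmin of deviations from the midpoint between the old and
#' new regime levels).  A candidate whose test window is truncated by
#' the series end but whose RSI stays positive is reported as
#' provisional.
#'
#' @param series Data frame with `time`, `value`; length must be at
#'   least `cutoff_l` (twice that is recommended).
#' @param cutoff_l Regime cut-off length `l` in time steps (100 for
#'   annual records, 800 for coarse Holocene series).
#' @param alpha Significance level of the sequential t-test (default
#'   0.1).
#' @param huber_h Huber weight parameter (default 1).
#' @param prewhiten Remove estimated lag-1 red noise first (see
#'   [prewhiten_ar1()])?
#' @param subsample_frac Subsample fraction for the red-noise estimate.
#' @return A `regime_shift` object; see [tidy.regime_shift()] for the
#'   per-regime table.  Elements include `change_points` (times of
#'   confirmed shifts), `rsi` values, `provisional` flags,
#'   `regime_means`, `sigma_l`, `diff` and `ar1_hat`.
#' @examples
#' seg <- data.frame(length = c(250, 250), mean = c(0, 2))
#' s <- gen_regime_series(seg, ar1 = 0.3, seed = 42)
#' fit <- detect_regimes(s, cutoff_l = 100)
#' tidy(fit)
#' @export
detect_regimes <- function(series, cutoff_l, alpha = 0.1, huber_h = 1,
                           prewhiten = FALSE, subsample_frac = 0.5) {
  series <- as_proxy_series(series)
  l <- check_count(cutoff_l, "cutoff_l", lower = 2L)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  if (huber_h <= 0) stop_invalid("`huber_h` must be > 0")

  ar1_hat <- NA_real_
  if (prewhiten) {
    pw <- prewhiten_ar1(series, cutoff_l = l, subsample_frac = subsample_frac)
    series <- pw$series
    ar1_hat <- pw$ar1_hat
  }
  x <- series$value
  n <- length(x)
  if (n < l) stop_invalid("series shorter than the cut-off length")

  sig <- sigma_l(x, l)
  dif <- threshold_diff(l, alpha, sig)

  cp_idx <- integer(0)
  rsi_vals <- numeric(0)
  provisional <- logical(0)
  regime_start <- 1L

  if (sig > 0) {
    # regime mean uses at least the first l points of the regime
    # (lookahead while the regime is young), then grows with it
    mu_over <- function(from, upto) {
      hi <- max(upto, min(from + l - 1L, n))
      huber_mean(x[from:hi], sig, huber_h)
    }
    mu <- mu_over(regime_start, regime_start)
    i <- l + 1L                      # scan starts after the initial window
    while (i <= n) {
      dev <- x[i] - mu
      if (abs(dev) > dif) {
        dir <- sign(dev)
        level <- mu + dir * dif
        jmax <- min(i + l - 1L, n)
        rsi <- 0
        ok <- TRUE
        for (j in i:jmax) {
          z <- (x[j] - level) / sig
          w <- huber_weight(z, huber_h)
          rsi <- rsi + dir * w * z / l
          if (rsi < 0) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          # the confirmation establishes that a shift occurred; its time
          # is then estimated by the usual change-point localizer --
          # iterated two-means segmentation of the test window (CUSUM
          # argmin against the midpoint of the two regime levels)
          cstar <- i
          for (it in 1:5) {
            m_new <- huber_mean(x[cstar:jmax], sig, huber_h)
            mid <- (mu + m_new) / 2
            S <- cumsum(dir * (x[i:jmax] - mid))
            k <- which.min(c(0, S)) - 1L
            cnew <- min(i + k, jmax)
            if (cnew == cstar) break
            cstar <- cnew
          }
          cp_idx <- c(cp_idx, cstar)
          rsi_vals <- c(rsi_vals, rsi)
          provisional <- c(provisional, jmax < i + l - 1L)
          regime_start <- cstar
          mu <- mu_over(regime_start, i)
          i <- max(i, cstar)
        } else {
          mu <- mu_over(regime_start, i)
        }
      } else {
        mu <- mu_over(regime_start, i)
      }
      i <- i + 1L
    }
  }

  bounds <- c(1L, cp_idx, n + 1L)
  regime_means <- vapply(seq_len(length(bounds) - 1L), function(k) {
    idx <- bounds[k]:(bounds[k + 1L] - 1L)
    huber_mean(x[idx], sig, huber_h)
  }, numeric(1))

  structure(
    list(
      series = series,
      change_points = series$time[cp_idx],
      change_index = cp_idx,
      rsi = rsi_vals,
      provisional = provisional,
      regime_means = regime_means,
      sigma_l = sig,
      diff = dif,
      ar1_hat = ar1_hat,
      config = list(cutoff_l = l, alpha = alpha, huber_h = huber_h,
                    prewhiten = prewhiten, subsample_frac = subsample_frac)
    ),
    class = "regime_shift"
  )
}

#' @export
print.regime_shift <- function(x, ...) {
  cat(sprintf(
    "# regime shift analysis: %d confirmed shift(s)%s (l = %d, alpha = %g)\n",
    sum(!x$provisional),
    if (any(x$provisional)) sprintf(" + %d provisional", sum(x$provisional)) else "",
    x$config$cutoff_l, x$config$alpha
  ))
  if (length(x$change_points)) {
    cat("  shifts at:", paste(signif(x$change_points, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-regime summary of a regime shift analysis
#'
#' @param x A `regime_shift` object from [detect_regimes()].
#' @param ... Unused.
#' @return Tibble with one row per regime: `start`, `end` (times),
#'   `n` points, Huber-weighted `mean`, and for every regime after the
#'   first the `rsi` of the confirming shift and its `provisional` flag.
#' @export
tidy.regime_shift <- function(x, ...) {
  bounds <- c(1L, x$change_index, nrow(x$series) + 1L)
  k <- length(bounds) - 1L
  tibble::tibble(
    start = x$series$time[bounds[-length(bounds)]],
    end = x$series$time[bounds[-1L] - 1L],
    n = diff(bounds),
    mean = x$regime_means,
    rsi = c(NA_real_, x$rsi),
    provisional = c(NA, x$provisional)
  )
}

#' One-row summary of a regime shift analysis
#'
#' @param x A `regime_shift` object.
#' @param ... Unused.
#' @export
glance.regime_shift <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$series),
    n_shifts = sum(!x$provisional),
    n_provisional = sum(x$provisional),
    sigma_l = x$sigma_l,
    threshold_diff = x$diff,
    ar1_hat = x$ar1_hat,
    cutoff_l = x$config$cutoff_l,
    alpha = x$config$alpha
  )
}
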