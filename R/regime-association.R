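#' Label years cold or warm from a regime segmentation
#'
#' Each year of a temperature series inherits the label of its regime:
#' cold when the regime's (Huber-weighted) mean lies below the overall
#' series mean, warm otherwise.
#'
#' @param seg A `regime_shift` object from [detect_regimes()] fitted to
#'   a temperature series.
#' @param series Optional data frame with `time`, `value`; defaults to
#'   the series stored in `seg`.
#' @return A `regime_labels` tibble with columns `year` and `label`
#'   (`"cold"` / `"warm"`).
#' @export
label_years <- function(seg, series = NULL) {
  if (!inherits(seg, "regime_shift")) {
    stop_invalid("`seg` must be a regime_shift object")
  }
  series <- if (is.null(series)) seg$series else as_proxy_series(series)
  if (min(series$time) < min(seg$series$time) ||
      max(series$time) > max(seg$series$time)) {
    stop_invalid("series years fall outside the segmentation span")
  }
  regimes <- tidy(seg)
  overall <- mean(seg$series$value)
  idx <- findInterval(series$time, regimes$start)
  lab <- ifelse(regimes$mean[idx] < overall, "cold", "warm")
  out <- tibble::tibble(year = series$time, label = lab)
  class(out) <- c("regime_labels", class(out))
  out
}

#' Bootstrap test of large-fire-year clustering in cold regimes
#'
#' Tests whether event years (LFYs) fall in cold regimes more often than
#' chance.  The observed statistic is `count(cold) - count(warm)` over
#' the event years.  The null resamples the same number of years
#' uniformly (with replacement by default) from all labeled years 1000
#' times, preserving the regime durations; the one-sided p-value is the
#' fraction of null differences at least as large as observed.  The 95%
#' interval and the 99.9% quantile of the null distribution are
#' reported.
#'
#' @param lfy_years Integer vector of event years, all within
#'   `labels$year`.
#' @param labels A [label_years()] result (tibble with `year`, `label`).
#' @param n_boot Number of bootstrap draws (>= 100; default 1000).
#' @param seed Integer seed for the resampling.
#' @param replace Resample years with replacement (`TRUE`, the default)
#'   or as a without-replacement permutation draw.
#' @return An `lfy_regime_test` object; see [glance.lfy_regime_test()].
#' @examples
#' labels <- tibble::tibble(year = 1:100,
#'                          label = rep(c("cold", "warm"), each = 50))
#' class(labels) <- c("regime_labels", class(labels))
#' bootstrap_lfy_test(c(3, 10, 22, 41, 47), labels, seed = 1)
#' @export
bootstrap_lfy_test <- function(lfy_years, labels, n_boot = 1000,
                               seed = NULL, replace = TRUE) {
  if (!is.data.frame(labels) || !all(c("year", "label") %in% names(labels))) {
    stop_invalid("`labels` must have columns `year` and `label`")
  }
  n_boot <- check_count(n_boot, "n_boot", lower = 100L)
  lfy_years <- as.numeric(lfy_years)
  if (length(lfy_years) < 1L) stop_invalid("need at least one event year")
  if (!all(lfy_years %in% labels$year)) {
    stop_invalid("every event year must lie in the labeled span")
  }
  is_cold <- labels$label == "cold"
  obs_cold <- sum(is_cold[match(lfy_years, labels$year)])
  k <- length(lfy_years)
  obs_diff <- obs_cold - (k - obs_cold)

  null_diffs <- with_seed_(seed, {
    cold <- if (replace) {
      colSums(matrix(sample(is_cold, k * n_boot, replace = TRUE), nrow = k))
    } else {
      vapply(seq_len(n_boot), function(b) {
        sum(sample(is_cold, k, replace = FALSE))
      }, numeric(1))
    }
    as.integer(2L * cold - k)
  })

  structure(
    list(
      observed_cold = obs_cold,
      observed_warm = k - obs_cold,
      observed_diff = obs_diff,
      null_diffs = null_diffs,
      ci95 = unname(quantile(null_diffs, c(0.025, 0.975))),
      quantile_999 = unname(quantile(null_diffs, 0.999)),
      p_value = mean(null_diffs >= obs_diff),
      n_boot = n_boot,
      n_events = k,
      seed = seed,
      replace = replace
    ),
    class = "lfy_regime_test"
  )
}

#' @export
print.lfy_regime_test <- function(x, ...) {
  cat(sprintf(
    paste0("# LFY cold/warm bootstrap: %d cold vs %d warm (diff %d); ",
           "null 95%% CI [%g, %g], 99.9%% quantile %g, one-sided p = %.4g\n"),
    x$observed_cold, x$observed_warm, x$observed_diff,
    x$ci95[1], x$ci95[2], x$quantile_999, x$p_value
  ))
  invisible(x)
}

#' Null distribution of the bootstrap test
#'
#' @param x An `lfy_regime_test` object.
#' @param ... Unused.
#' @return Tibble with one row per bootstrap draw (`null_diff`).
#' @export
tidy.lfy_regime_test <- function(x, ...) {
  tibble::tibble(null_diff = x$null_diffs)
}

#' One-row summary of the bootstrap test
#'
#' @param x An `lfy_regime_test` object.
#' @param ... Unused.
#' @export
glance.lfy_regime_test <- function(x, ...) {
  tibble::tibble(
    observed_cold = x$observed_cold,
    observed_warm = x$observed_warm,
    observed_diff = x$observed_diff,
    ci95_low = x$ci95[1],
    ci95_high = x$ci95[2],
    quantile_999 = x$quantile_999,
    p_value = x$p_value,
    n_boot = x$n_boot,
    n_events = x$n_events
  )
}
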