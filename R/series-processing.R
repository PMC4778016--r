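#' Normalize a fire series
#'
#' Log (`log1p`) or square-root transform of a non-negative fire record,
#' used to bring heavily skewed burned-area data toward normality before
#' correlation analysis.
#'
#' @param series Data frame with `time`, `value`; values must be >= 0.
#' @param method `"log1p"` (natural log of 1 + x, so zeros map to zero)
#'   or `"sqrt"`.
#' @return A transformed [proxy_series()]; the method is recorded in the
#'   label.
#' @export
transform_fire <- function(series, method = c("log1p", "sqrt")) {
  series <- as_proxy_series(series)
  method <- match.arg(method)
  v <- series$value
  if (any(v[is.finite(v)] < 0)) {
    stop_invalid("fire values must be non-negative")
  }
  out <- switch(method, log1p = log1p(v), sqrt = sqrt(v))
  proxy_series(series$time, out, resolution = series_resolution(series),
               label = paste0(method, "(", series_label(series), ")"))
}

#' Standardize a series to zero mean and unit variance
#'
#' z-scores with the sample standard deviation, so that sites receive
#' equal weight when composited.
#'
#' @param series Data frame with `time`, `value` and at least two
#'   distinct values.
#' @return A standardized [proxy_series()] (mean 0, sd 1).
#' @export
standardize <- function(series) {
  series <- as_proxy_series(series)
  v <- series$value
  s <- sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("cannot standardize a constant series")
  }
  proxy_series(series$time, (v - mean(v, na.rm = TRUE)) / s,
               resolution = series_resolution(series),
               label = paste0("z(", series_label(series), ")"))
}

bin_edges <- function(time, bin_width, origin = NULL) {
  origin <- origin %||% min(time)
  lo <- floor((min(time) - origin) / bin_width)
  hi <- floor((max(time) - origin) / bin_width)
  origin + (lo:(hi + 1)) * bin_width
}

#' Aggregate a series to a constant coarser resolution
#'
#' Bins are left-closed, right-open intervals of width `bin_width`
#' anchored at the earliest covered time (or a supplied `origin`).  Empty
#' bins yield missing values.
#'
#' @param series Data frame with `time`, `value`.
#' @param bin_width Bin width in years, larger than the series
#'   resolution.
#' @param aggregator `"mean"` or `"sum"` within each bin.
#' @param origin Optional bin anchor (a time at which a bin starts).
#' @return A [proxy_series()] timestamped at bin starts with
#'   `resolution = bin_width`.
#' @export
bin_series <- function(series, bin_width, aggregator = c("mean", "sum"),
                       origin = NULL) {
  series <- as_proxy_series(series)
  aggregator <- match.arg(aggregator)
  check_number(bin_width, "bin_width")
  if (bin_width <= 0) stop_invalid("`bin_width` must be > 0")
  if (bin_width <= series_resolution(series)) {
    stop_invalid("`bin_width` must exceed the series resolution")
  }
  edges <- bin_edges(series$time, bin_width, origin)
  idx <- findInterval(series$time, edges, rightmost.closed = FALSE)
  starts <- edges[-length(edges)]
  fun <- if (aggregator == "mean") mean else sum
  vals <- as.numeric(
    tapply(series$value, factor(idx, levels = seq_along(starts)), fun)
  )
  proxy_series(starts, vals, resolution = bin_width,
               label = paste0(aggregator, "-binned ", series_label(series)))
}

#' Composite several sites into one standardized binned record
#'
#' Each site series is standardized (equal weight per site), binned onto
#' a common grid anchored at the earliest time covered by any site, and
#' averaged per bin over the sites with data in that bin.
#'
#' @param series_list List of data frames with `time`, `value`.
#' @param bin_width Common bin width in years.
#' @return A `binned_composite` tibble with columns `bin_start`, `value`
#'   and `n_sites` (sites contributing per bin); bins with no data are
#'   dropped.  `bin_width` is carried as an attribute.
#' @export
composite <- function(series_list, bin_width) {
  if (!is.list(series_list) || length(series_list) < 1L) {
    stop_invalid("`series_list` must be a non-empty list of series")
  }
  series_list <- lapply(series_list, as_proxy_series)
  origin <- min(vapply(series_list, function(s) min(s$time), numeric(1)))
  binned <- lapply(series_list, function(s) {
    bin_series(standardize(s), bin_width, "mean", origin = origin)
  })
  all_starts <- sort(unique(unlist(lapply(binned, function(b) b$time))))
  acc_sum <- numeric(length(all_starts))
  acc_n <- integer(length(all_starts))
  for (b in binned) {
    j <- match(b$time, all_starts)
    has <- !is.na(b$value)
    acc_sum[j[has]] <- acc_sum[j[has]] + b$value[has]
    acc_n[j[has]] <- acc_n[j[has]] + 1L
  }
  keep <- acc_n > 0L
  if (!any(keep)) stop_degenerate("no bin has data from any site")
  out <- tibble::tibble(
    bin_start = all_starts[keep],
    value = acc_sum[keep] / acc_n[keep],
    n_sites = acc_n[keep]
  )
  attr(out, "bin_width") <- bin_width
  class(out) <- c("binned_composite", class(out))
  out
}

#' Remove the long-term linear trend
#'
#' Ordinary least-squares line on (time, value), residuals returned.
#' Residuals have zero mean and zero covariance with time.
#'
#' @param series Data frame with `time`, `value` and >= 3 points.
#' @return A detrended [proxy_series()].
#' @export
detrend_linear <- function(series) {
  series <- as_proxy_series(series)
  if (nrow(series) < 3L) {
    stop_degenerate("need at least 3 points to detrend")
  }
  fit <- lm(value ~ time, data = series)
  proxy_series(series$time, as.numeric(stats::residuals(fit)),
               resolution = series_resolution(series),
               label = paste0("detrended ", series_label(series)))
}

#' Moving cumulative burned area
#'
#' Sums an annual burned-area record over a moving window (default 100
#' years) advanced in steps (default 10 years), producing the smoothed
#' decadal-resolution fire chronology used as input to regime shift
#' analysis.
#'
#' @param series Annual data frame with `time`, `value`.
#' @param window Window length in years.
#' @param step Advance between windows in years.
#' @return A [proxy_series()] of window sums, timestamped at window start
#'   years, with `resolution = step`.
#' @export
moving_cumulative <- function(series, window = 100, step = 10) {
  series <- as_proxy_series(series)
  window <- check_count(window, "window")
  step <- check_count(step, "step")
  if (series_resolution(series) != 1) {
    stop_invalid("`moving_cumulative` expects an annual series")
  }
  n <- nrow(series)
  if (window > n) stop_invalid("`window` exceeds the series length")
  starts <- seq(1L, n - window + 1L, by = step)
  cs <- cumsum(c(0, series$value))
  sums <- cs[starts + window] - cs[starts]
  proxy_series(series$time[starts], sums, resolution = step,
               label = paste0("cumulative ", window, "-yr ",
                              series_label(series)))
}

# shifted Box-Cox power transform; lambda fitted by profile likelihood
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

fit_boxcox_lambda <- function(y, interval = c(-2, 2)) {
  if (diff(range(y)) == 0) return(1)   # constant site: transform is moot
  loglik <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    s2 <- mean((z - mean(z))^2)
    -length(y) / 2 * log(s2) + (lambda - 1) * sum(log(y))
  }
  stats::optimize(loglik, interval = interval, maximum = TRUE)$maximum
}

#' Prepare charcoal series and build a regional composite
#'
#' Per-site conditioning chain for sediment-charcoal records: optional
#' influx conversion (concentration times deposition rate), a shifted
#' Box-Cox power transform (shift = 1% of the site maximum, so zeros are
#' admitted), standardization, then compositing at a coarse bin width
#' (default 200 years) via [composite()].
#'
#' @param series_list List of charcoal series (data frames with `time`,
#'   `value`), concentrations or influx.
#' @param deposition_rates Optional list of numeric vectors (one per
#'   site, same length as the site series) multiplying values into
#'   influx.
#' @param bin_width Composite bin width in years.
#' @param lambda Optional fixed Box-Cox exponent; fitted per site by
#'   maximum likelihood when `NULL`.
#' @return A `binned_composite` tibble (see [composite()]).
#' @export
charcoal_prepare <- function(series_list, deposition_rates = NULL,
                             bin_width = 200, lambda = NULL) {
  if (!is.list(series_list) || length(series_list) < 1L) {
    stop_invalid("`series_list` must be a non-empty list of series")
  }
  series_list <- lapply(series_list, as_proxy_series)
  prepared <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    v <- s$value
    if (!is.null(deposition_rates)) {
      dr <- deposition_rates[[i]]
      if (length(dr) != length(v)) {
        stop_invalid("deposition rate vector must match the site series length")
      }
      v <- v * dr
    }
    shift <- 0.01 * max(v)
    y <- v + shift
    if (any(y <= 0)) {
      stop_invalid("non-positive charcoal values after shift")
    }
    lam <- lambda %||% fit_boxcox_lambda(y)
    proxy_series(s$time, boxcox_transform(y, lam),
                 resolution = series_resolution(s),
                 label = series_label(s))
  })
  composite(prepared, bin_width)
}
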