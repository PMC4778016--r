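#' Seasonal average of a monthly field
#'
#' Averages the listed months within each calendar year at every grid
#' cell, producing an annual field (e.g. April-May SST).  Years missing
#' any of the requested months are dropped.
#'
#' @param field A monthly [gridded_field()].
#' @param months Integer months (subset of 1..12).
#' @return An annual [gridded_field()].
#' @export
seasonal_index <- function(field, months) {
  if (!inherits(field, "gridded_field")) {
    stop_invalid("`field` must be a gridded_field")
  }
  if (!is_monthly(field)) stop_invalid("`field` is already annual")
  months <- as.integer(months)
  if (length(months) < 1L || any(months < 1L | months > 12L)) {
    stop_invalid("`months` must be a subset of 1..12")
  }
  keep <- field$month %in% months
  yrs <- sort(unique(field$year[keep]))
  complete <- vapply(yrs, function(y) {
    sum(keep & field$year == y) == length(unique(months))
  }, logical(1))
  yrs <- yrs[complete]
  if (length(yrs) == 0L) stop_invalid("no year has all requested months")
  m <- field_matrix(field)
  out <- t(vapply(yrs, function(y) {
    colMeans(m[keep & field$year == y, , drop = FALSE])
  }, numeric(ncol(m))))
  gridded_field(array(out, dim = c(length(yrs), length(field$lat),
                                   length(field$lon))),
                lat = field$lat, lon = field$lon, year = yrs,
                units = field$units)
}

#' Effective sample size under lag-1 autocorrelation
#'
#' Reduces the nominal sample size of a correlation between two
#' autocorrelated series: `n_eff = n (1 - r1_a r1_b) / (1 + r1_a r1_b)`,
#' floored at 3 and capped at `n`.
#'
#' @param n Nominal number of paired observations.
#' @param r1_a,r1_b Lag-1 autocorrelations of the two series
#'   (vectorized over `r1_b`).
#' @return Effective sample size(s).
#' @export
effective_n <- function(n, r1_a, r1_b) {
  n <- check_number(n, "n", lower = 1)
  if (any(abs(r1_a) >= 1, na.rm = TRUE) || any(abs(r1_b) >= 1, na.rm = TRUE)) {
    stop_invalid("lag-1 autocorrelations must lie inside (-1, 1)")
  }
  prod <- r1_a * r1_b
  ne <- n * (1 - prod) / (1 + prod)
  pmin(n, pmax(3, ne))
}

# two-sided p of a Pearson r at effective sample size ne
r_to_p <- function(r, ne) {
  df <- ne - 2
  r2 <- pmin(r^2, 1 - 1e-15)
  t <- abs(r) * sqrt(df / (1 - r2))
  2 * pt(t, df, lower.tail = FALSE)
}

# columnwise Pearson r of vector z (standardized) against matrix Z of
# standardized columns, both over n rows
cor_with_index <- function(zi, Z) {
  as.vector(crossprod(zi, Z)) / (length(zi) - 1)
}

# columnwise lag-1 autocorrelation
col_lag1 <- function(X) {
  n <- nrow(X)
  a <- X[-n, , drop = FALSE]
  b <- X[-1, , drop = FALSE]
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  r1 <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(r1, -0.999), 0.999)
}

#' Correlation map of an index against a gridded field
#'
#' Pearson correlation of a scalar index with every grid cell over the
#' overlapping years, with two refinements: (i) local significance uses
#' a two-sided t-test at the [effective_n()] reduced by the lag-1
#' autocorrelations of both series, and (ii) the map-wide result is
#' summarized by field significance -- the observed fraction of locally
#' significant cells is compared against `n_perm` random permutations of
#' the index years, which preserves the field's spatial correlation.
#'
#' @param index Data frame with `time`, `value` (annual).
#' @param field A [gridded_field()]; monthly fields are first averaged
#'   over `months`.
#' @param months Months to average for monthly fields; ignored (may be
#'   `NULL`) for annual fields.
#' @param alpha Local significance level (default 0.1).
#' @param n_perm Number of index permutations for field significance.
#' @param seed Integer seed for the permutations.
#' @return A `correlation_map` object with matrices `r`, `p_adj`,
#'   `n_eff` (lat x lon), scalars `p_field` and `frac_significant`, and
#'   metadata.  See [tidy.correlation_map()].
#' @examples
#' idx <- gen_ar1_series(60, seed = 1)
#' f <- gen_teleconnected_field(idx, 8, 10, c(2, 4), c(3, 6), 0.6,
#'                              seed = 2)
#' cm <- correlation_map(idx, f, n_perm = 99, seed = 3)
#' cm$p_field
#' @export
correlation_map <- function(index, field, months = NULL, alpha = 0.1,
                            n_perm = 1000, seed = NULL) {
  index <- as_proxy_series(index)
  if (!inherits(field, "gridded_field")) {
    stop_invalid("`field` must be a gridded_field")
  }
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  n_perm <- check_count(n_perm, "n_perm")
  if (is_monthly(field)) {
    if (is.null(months)) stop_invalid("`months` required for a monthly field")
    field <- seasonal_index(field, months)
  }
  yrs <- intersect(round(index$time), field$year)
  if (length(yrs) < 10L) {
    stop_invalid("need at least 10 overlapping years")
  }
  iv <- index$value[match(yrs, round(index$time))]
  X <- field_matrix(field)[match(yrs, field$year), , drop = FALSE]
  n <- length(yrs)

  cell_ok <- apply(is.finite(X), 2, all)
  Z <- X[, cell_ok, drop = FALSE]
  Zc <- scale(Z)
  const <- !is.finite(colSums(Zc)) | apply(Z, 2, sd) == 0
  Zc[, const] <- 0

  r1_cells <- col_lag1(Z)
  zi <- as.vector(scale(iv))
  r1_idx <- lag1_cor(iv)

  map_p <- function(z_index, r1_index) {
    r <- cor_with_index(z_index, Zc)
    ne <- effective_n(n, r1_index, r1_cells)
    list(r = r, p = r_to_p(r, ne), ne = ne)
  }
  obs <- map_p(zi, r1_idx)
  frac_sig <- mean(obs$p <= alpha, na.rm = TRUE)

  perm_frac <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b) {
      pv <- iv[sample.int(n)]
      pm <- map_p(as.vector(scale(pv)), lag1_cor(pv))
      mean(pm$p <= alpha, na.rm = TRUE)
    }, numeric(1))
  })
  p_field <- mean(perm_frac >= frac_sig)

  expand_cells <- function(v) {
    out <- rep(NA_real_, length(cell_ok))
    out[cell_ok] <- v
    matrix(out, nrow = length(field$lat))
  }
  structure(
    list(
      r = expand_cells(obs$r),
      p_adj = expand_cells(obs$p),
      n_eff = expand_cells(obs$ne),
      lat = field$lat, lon = field$lon,
      p_field = p_field, frac_significant = frac_sig,
      months = months, alpha = alpha, n = n, n_perm = n_perm, seed = seed
    ),
    class = "correlation_map"
  )
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    paste0("# correlation map: %d x %d cells over %d yr; %.1f%% locally ",
           "significant at alpha = %g; p_field = %.4g\n"),
    length(x$lat), length(x$lon), x$n, 100 * x$frac_significant,
    x$alpha, x$p_field
  ))
  invisible(x)
}

#' Long tibble view of a correlation map
#'
#' @param x A `correlation_map` object.
#' @param ... Unused.
#' @return Tibble with one row per cell: `lat`, `lon`, `r`, `p_adj`,
#'   `n_eff`, `significant`.
#' @export
tidy.correlation_map <- function(x, ...) {
  g <- expand.grid(lat = x$lat, lon = x$lon, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    lat = g$lat, lon = g$lon,
    r = as.vector(x$r),
    p_adj = as.vector(x$p_adj),
    n_eff = as.vector(x$n_eff),
    significant = as.vector(x$p_adj) <= x$alpha
  )
}

#' One-row summary of a correlation map
#'
#' @param x A `correlation_map` object.
#' @param ... Unused.
#' @export
glance.correlation_map <- function(x, ...) {
  tibble::tibble(
    n_years = x$n,
    n_cells = sum(is.finite(x$r)),
    frac_significant = x$frac_significant,
    p_field = x$p_field,
    alpha = x$alpha,
    n_perm = x$n_perm,
    mean_r = mean(x$r, na.rm = TRUE),
    min_r = min(x$r, na.rm = TRUE),
    max_r = max(x$r, na.rm = TRUE)
  )
}

#' Moving-window correlation between two series
#'
#' Pearson correlation in sliding windows over the common years,
#' checking the temporal stability of a teleconnection.
#'
#' @param index,series Data frames with `time`, `value`.
#' @param window Window length in time steps (default 31).
#' @param step Advance between windows (default 1).
#' @return A [proxy_series()] of correlations timestamped at window
#'   centers; windows in which either series is constant yield `NA`.
#' @export
moving_correlation <- function(index, series, window = 31, step = 1) {
  index <- as_proxy_series(index)
  series <- as_proxy_series(series)
  window <- check_count(window, "window", lower = 3L)
  step <- check_count(step, "step")
  t_common <- intersect(index$time, series$time)
  if (length(t_common) < window) {
    stop_invalid("`window` exceeds the overlap length")
  }
  t_common <- sort(t_common)
  a <- index$value[match(t_common, index$time)]
  b <- series$value[match(t_common, series$time)]
  starts <- seq(1L, length(t_common) - window + 1L, by = step)
  r <- vapply(starts, function(s) {
    ia <- a[s:(s + window - 1L)]
    ib <- b[s:(s + window - 1L)]
    if (sd(ia) == 0 || sd(ib) == 0) return(NA_real_)
    cor(ia, ib)
  }, numeric(1))
  centers <- t_common[starts] + (window - 1) / 2
  proxy_series(centers, r, resolution = step,
               label = sprintf("moving r (window %d)", window))
}

#' Superposed epoch analysis of a gridded field
#'
#' Composites the field over a set of event years and tests the mean
#' anomaly cell by cell: for each requested month, the composite anomaly
#' is the event-year mean minus the all-year climatology, and its
#' two-sided p-value is the fraction of `n_boot` random draws of equally
#' many years (without replacement) whose composite magnitude is at
#' least the observed one.
#'
#' @param field A [gridded_field()] (monthly or annual; annual fields
#'   use `months = NULL`).
#' @param event_years Integer vector of at least 2 event years inside
#'   the field's span.
#' @param months Months to analyze for monthly fields.
#' @param n_boot Number of random year draws.
#' @param seed Integer seed.
#' @return An `sea_result` with arrays `composite` and `p` of dim
#'   `(month, lat, lon)`; see [tidy.sea_result()].
#' @export
sea <- function(field, event_years, months = NULL, n_boot = 1000,
                seed = NULL) {
  if (!inherits(field, "gridded_field")) {
    stop_invalid("`field` must be a gridded_field")
  }
  n_boot <- check_count(n_boot, "n_boot", lower = 100L)
  event_years <- as.integer(event_years)
  if (length(event_years) < 2L) stop_invalid("need at least 2 event years")
  month_list <- if (is_monthly(field)) {
    if (is.null(months)) stop_invalid("`months` required for a monthly field")
    as.integer(months)
  } else NA_integer_
  nla <- length(field$lat)
  nlo <- length(field$lon)
  nm <- length(month_list)
  comp <- array(NA_real_, dim = c(nm, nla, nlo))
  pval <- array(NA_real_, dim = c(nm, nla, nlo))

  draws_for <- function(n_years, k) {
    with_seed_(seed, {
      t(vapply(seq_len(n_boot), function(b) sample.int(n_years, k),
               integer(k)))
    })
  }

  for (mi in seq_len(nm)) {
    f <- if (is_monthly(field)) {
      seasonal_index(field, month_list[mi])
    } else {
      field
    }
    if (!all(event_years %in% f$year)) {
      stop_invalid("every event year must lie inside the field's span")
    }
    A <- field_matrix(f)
    A <- sweep(A, 2, colMeans(A))          # anomalies from climatology
    ev <- match(event_years, f$year)
    obs <- colMeans(A[ev, , drop = FALSE])
    idx <- draws_for(nrow(A), length(ev))
    exceed <- numeric(ncol(A))
    for (b in seq_len(n_boot)) {
      boot <- colMeans(A[idx[b, ], , drop = FALSE])
      exceed <- exceed + (abs(boot) >= abs(obs))
    }
    comp[mi, , ] <- matrix(obs, nrow = nla)
    pval[mi, , ] <- matrix(exceed / n_boot, nrow = nla)
  }

  structure(
    list(composite = comp, p = pval, months = month_list,
         lat = field$lat, lon = field$lon,
         event_years = event_years, n_boot = n_boot, seed = seed),
    class = "sea_result"
  )
}

#' @export
print.sea_result <- function(x, ...) {
  cat(sprintf(
    "# superposed epoch analysis: %d event years, %d month window(s), %d x %d cells\n",
    length(x$event_years), length(x$months), length(x$lat), length(x$lon)
  ))
  invisible(x)
}

#' Long tibble view of a superposed epoch analysis
#'
#' @param x An `sea_result` object.
#' @param ... Unused.
#' @return Tibble with one row per month and cell: `month`, `lat`,
#'   `lon`, `composite`, `p`.
#' @export
tidy.sea_result <- function(x, ...) {
  nla <- length(x$lat)
  nlo <- length(x$lon)
  nm <- length(x$months)
  tibble::tibble(
    month = rep(x$months, times = nla * nlo),
    lat = rep(rep(x$lat, each = nm), times = nlo),
    lon = rep(x$lon, each = nm * nla),
    composite = as.vector(x$composite),
    p = as.vector(x$p)
  )
}
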