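#' Generate a stationary AR(1) series
#'
#' Red-noise generator used as the null model throughout: a first-order
#' autoregression with lag-1 coefficient `ar1`, innovations scaled so the
#' marginal standard deviation is `sd`, and the first value drawn from
#' the stationary distribution (no burn-in transient).
#'
#' @param n Series length (years), at least 2.
#' @param mean Marginal mean.
#' @param ar1 Lag-1 coefficient, strictly inside (-1, 1).
#' @param sd Marginal standard deviation, > 0.
#' @param seed Integer seed; identical seeds give bit-identical series.
#' @param start_year First calendar year of the time axis.
#' @param label Series label.
#' @return A [proxy_series()] of length `n` at annual resolution.
#' @examples
#' s <- gen_ar1_series(200, ar1 = 0.5, seed = 1)
#' @export
gen_ar1_series <- function(n, mean = 0, ar1 = 0, sd = 1, seed = NULL,
                           start_year = 1, label = "ar1") {
  n <- check_count(n, "n", lower = 2L)
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0)
  if (!is.numeric(ar1) || length(ar1) != 1L || abs(ar1) >= 1) {
    stop_invalid("`ar1` must lie strictly inside (-1, 1)")
  }
  x <- with_seed_(seed, {
    innov_sd <- sd * sqrt(1 - ar1^2)
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd)          # stationary start
    e <- rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- ar1 * x[t - 1] + e[t - 1]
    x
  })
  proxy_series(start_year + seq_len(n) - 1, mean + x,
               resolution = 1, label = label)
}

#' Generate an AR(1) series with step changes in the mean
#'
#' Superposes stationary AR(1) noise on a piecewise-constant mean: the
#' canonical test input for the regime shift detector, emulating periods
#' of similar mean conditions separated by abrupt shifts.
#'
#' @param segments Data frame with columns `length` (>= 1) and `mean`,
#'   one row per regime in order; an optional `start_index` column
#'   (0-based) is checked for contiguity.
#' @inheritParams gen_ar1_series
#' @return A [proxy_series()] whose length is the sum of segment lengths.
#' @examples
#' seg <- data.frame(length = c(100, 100), mean = c(0, 2))
#' s <- gen_regime_series(seg, ar1 = 0.3, seed = 7)
#' @export
gen_regime_series <- function(segments, ar1 = 0, sd = 1, seed = NULL,
                              start_year = 1, label = "regime series") {
  if (!is.data.frame(segments) || nrow(segments) < 1L ||
      !all(c("length", "mean") %in% names(segments))) {
    stop_invalid("`segments` must be a data frame with columns length, mean")
  }
  len <- as.integer(segments$length)
  if (any(len < 1L)) stop_invalid("segment lengths must be >= 1")
  if ("start_index" %in% names(segments)) {
    expected <- cumsum(c(0L, len[-length(len)]))
    if (!identical(as.integer(segments$start_index), expected)) {
      stop_invalid("segments must be contiguous and non-overlapping from index 0")
    }
  }
  n <- sum(len)
  if (n < 2L) stop_invalid("total series length must be >= 2")
  step_mean <- rep(segments$mean, times = len)
  noise <- gen_ar1_series(n, mean = 0, ar1 = ar1, sd = sd, seed = seed,
                          start_year = start_year)
  proxy_series(noise$time, noise$value + step_mean,
               resolution = 1, label = label)
}

#' Simulate a multi-site fire record with planted large fire years
#'
#' Each site-year burns independently: with probability `base_p` in
#' ordinary years and the inflated probability `lfy_p` in the planted
#' large-fire years.  All sites are recording throughout, so the per-year
#' burn count is binomial -- exactly the null model of [detect_lfy()].
#'
#' @param n_years,n_sites Record dimensions.
#' @param base_p Per-site burn probability in ordinary years.
#' @param lfy_years Integer positions (1-based within the record) of the
#'   planted large fire years.
#' @param lfy_p Per-site burn probability in planted years
#'   (`base_p <= lfy_p`).
#' @param seed Integer seed.
#' @param start_year First calendar year.
#' @return A [site_burn_matrix()] tibble.
#' @examples
#' m <- gen_site_burn_matrix(100, 20, 0.02, lfy_years = c(30, 60),
#'                           lfy_p = 0.4, seed = 1)
#' @export
gen_site_burn_matrix <- function(n_years, n_sites, base_p,
                                 lfy_years = integer(), lfy_p = base_p,
                                 seed = NULL, start_year = 1L) {
  n_years <- check_count(n_years, "n_years")
  n_sites <- check_count(n_sites, "n_sites")
  check_prob(base_p, "base_p")
  check_prob(lfy_p, "lfy_p")
  if (base_p > lfy_p) stop_invalid("`lfy_p` must be >= `base_p`")
  lfy_years <- as.integer(lfy_years)
  if (length(lfy_years) &&
      (any(lfy_years < 1L) || any(lfy_years > n_years))) {
    stop_invalid("`lfy_years` must index years within the record")
  }
  p_year <- rep(base_p, n_years)
  p_year[lfy_years] <- lfy_p
  burned <- with_seed_(seed, {
    matrix(runif(n_years * n_sites) < p_year, nrow = n_years)
  })
  years <- start_year + seq_len(n_years) - 1L
  sites <- sprintf("S%03d", seq_len(n_sites))
  site_burn_matrix(tibble::tibble(
    year = rep(years, times = n_sites),
    site = rep(sites, each = n_years),
    burned = as.vector(burned),
    recording = TRUE
  ))
}

#' Simulate a gridded field teleconnected to an index series
#'
#' Builds an annual lat/lon field of unit white noise in which a
#' rectangular block of cells carries a linear imprint of the index:
#' inside the block each cell is `coupling * z(index) + noise` with noise
#' standard deviation `noise_sd`, so the expected in-block correlation is
#' `coupling / sqrt(coupling^2 + noise_sd^2)` for a unit-variance index.
#' Cells outside the block are independent of the index.  This emulates a
#' localized centre of action embedded in a larger domain.
#'
#' @param index A series (data frame with `time`, `value`); its length
#'   sets the field's time axis.
#' @param nlat,nlon Grid dimensions.
#' @param block_lat,block_lon Integer index ranges `c(first, last)` of
#'   the coupled block, within the grid.
#' @param coupling Coupling coefficient in `[-1, 1]`.
#' @param noise_sd In-block noise standard deviation, > 0.
#' @param seed Integer seed.
#' @return An annual [gridded_field()] on a regular synthetic grid.
#' @examples
#' idx <- gen_ar1_series(50, seed = 1)
#' f <- gen_teleconnected_field(idx, 10, 15, c(3, 6), c(5, 9), 0.5, seed = 2)
#' @export
gen_teleconnected_field <- function(index, nlat, nlon,
                                    block_lat, block_lon,
                                    coupling, noise_sd = 1, seed = NULL) {
  index <- as_proxy_series(index)
  nlat <- check_count(nlat, "nlat")
  nlon <- check_count(nlon, "nlon")
  check_number(coupling, "coupling", -1, 1)
  check_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be > 0")
  block_lat <- as.integer(block_lat)
  block_lon <- as.integer(block_lon)
  ok_block <- function(b, nmax) {
    length(b) == 2L && b[1] >= 1L && b[2] >= b[1] && b[2] <= nmax
  }
  if (!ok_block(block_lat, nlat) || !ok_block(block_lon, nlon)) {
    stop_invalid("teleconnection block must lie inside the grid")
  }
  nt <- nrow(index)
  z <- as.vector(scale(index$value))
  vals <- with_seed_(seed, {
    v <- array(rnorm(nt * nlat * nlon), dim = c(nt, nlat, nlon))
    ila <- block_lat[1]:block_lat[2]
    ilo <- block_lon[1]:block_lon[2]
    block <- v[, ila, ilo, drop = FALSE] * noise_sd
    v[, ila, ilo] <- block + coupling * z
    v
  })
  gridded_field(vals,
                lat = seq(40, 80, length.out = nlat),
                lon = seq(-80, 30, length.out = nlon),
                year = round(index$time), units = "z")
}
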