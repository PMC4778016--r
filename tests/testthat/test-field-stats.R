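monthly_field <- function(years, months, fill) {
  nt <- length(years) * length(months)
  yr <- rep(years, each = length(months))
  mo <- rep(months, times = length(years))
  vals <- array(fill(nt), dim = c(nt, 2, 3))
  gridded_field(vals, lat = c(50, 60), lon = c(-30, -20, -10),
                year = yr, month = mo)
}

test_that("seasonal averaging extracts and averages the listed months", {
  f <- monthly_field(2001:2003, 1:12, function(n) rep(seq_len(n / 6), each = 6))
  one <- seasonal_index(f, 7)
  expect_equal(one$year, 2001:2003)
  expect_equal(one$values[, 1, 1],
               f$values[f$month == 7, 1, 1])

  # months [4, 5] holding values 2 and 4 average to 3
  f2 <- monthly_field(2001, 1:12, function(n) rep(0, n))
  f2$values[f2$month == 4, , ] <- 2
  f2$values[f2$month == 5, , ] <- 4
  avg <- seasonal_index(f2, c(4, 5))
  expect_true(all(avg$values == 3))
  expect_equal(seasonal_index(f2, c(4, 4))$values[1, 1, 1], 2)

  expect_error(seasonal_index(f, 13), class = "borealfire_invalid")
})

test_that("effective sample size follows the closed form with caps", {
  expect_equal(effective_n(100, 0, 0), 100)
  expect_equal(effective_n(100, 0.5, 0.5), 60)
  expect_equal(effective_n(100, -0.5, 0.5), 100)  # capped at n
  expect_equal(effective_n(4, 0.99, 0.99), 3)     # floored at 3
  expect_error(effective_n(100, 1, 0.2), class = "borealfire_invalid")
})

test_that("correlation maps recover exact and planted teleconnections", {
  idx <- gen_ar1_series(80, seed = 3)
  f <- gen_teleconnected_field(idx, 6, 8, c(2, 3), c(3, 5), 0,
                               seed = 4)
  # plant an exact copy of the index in one cell
  f$values[, 5, 7] <- idx$value
  cm <- correlation_map(idx, f, n_perm = 99, seed = 5)
  expect_equal(cm$r[5, 7], 1, tolerance = 1e-12)
  expect_lt(cm$p_adj[5, 7], 1e-10)

  # r is invariant under affine transforms of the index
  idx2 <- proxy_series(idx$time, -2 * idx$value + 5)
  cm2 <- correlation_map(idx2, f, n_perm = 99, seed = 5)
  expect_equal(abs(cm2$r), abs(cm$r), tolerance = 1e-12)

  # a coupled block is recovered with field significance
  ft <- gen_teleconnected_field(idx, 10, 12, c(3, 6), c(4, 8), 0.7,
                                noise_sd = 0.7, seed = 6)
  cmt <- correlation_map(idx, ft, n_perm = 199, seed = 7)
  expect_gt(mean(cmt$r[3:6, 4:8]), 0.4)
  expect_lt(cmt$p_field, 0.05)

  short <- proxy_series(1:5, rnorm(5))
  expect_error(correlation_map(short, f), class = "borealfire_invalid")
})

test_that("moving correlations track the windowed Pearson r", {
  a <- gen_ar1_series(120, seed = 8)
  same <- moving_correlation(a, a, window = 31)
  expect_true(all(abs(same$value - 1) < 1e-12))

  b <- gen_ar1_series(120, seed = 9)
  mc <- moving_correlation(a, b, window = 31)
  neg <- moving_correlation(a, proxy_series(b$time, -b$value), window = 31)
  expect_equal(neg$value, -mc$value, tolerance = 1e-12)
  expect_equal(mc$value[1],
               cor(a$value[1:31], b$value[1:31]), tolerance = 1e-12)

  null_r <- mean(vapply(1:20, function(s) {
    mean(moving_correlation(gen_ar1_series(100, seed = 100 + s),
                            gen_ar1_series(100, seed = 900 + s),
                            window = 31)$value)
  }, numeric(1)))
  expect_lt(abs(null_r), 0.1)

  expect_error(moving_correlation(a, b, window = 300),
               class = "borealfire_invalid")
})

test_that("superposed epoch composites are anomalies with seeded p-values", {
  idx <- gen_ar1_series(40, seed = 10)
  f <- gen_teleconnected_field(idx, 8, 10, c(2, 3), c(2, 3), 0, seed = 11)

  # compositing every year gives exactly zero anomalies
  full <- sea(f, f$year, n_boot = 100, seed = 12)
  expect_true(all(abs(full$composite) < 1e-12))

  # planted +1 sd anomaly in a block over 5 event years
  ev <- c(5, 12, 20, 28, 35) + f$year[1] - 1
  fb <- f
  fb$values[match(ev, f$year), 3:6, 4:8] <-
    fb$values[match(ev, f$year), 3:6, 4:8] + 1
  res <- sea(fb, ev, n_boot = 1000, seed = 13)
  block_comp <- res$composite[1, 3:6, 4:8]
  expect_lt(abs(mean(block_comp) - 1), 0.2)
  # per-cell power is limited by the 5-event composite noise (sd ~ 0.45
  # sd): the block flags far above the 10% background, not wall-to-wall
  expect_gte(mean(res$p[1, 3:6, 4:8] <= 0.10), 0.5)
  out_p <- res$p[1, 7:8, 1:3]
  expect_lte(mean(out_p <= 0.10), 0.35)

  expect_identical(sea(fb, ev, n_boot = 200, seed = 14)$p,
                   sea(fb, ev, n_boot = 200, seed = 14)$p)
  expect_error(sea(f, c(999, 1000), n_boot = 100, seed = 1),
               class = "borealfire_invalid")
})
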