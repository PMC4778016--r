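series_of <- function(values, start = 1) {
  proxy_series(seq(start, by = 1, length.out = length(values)), values)
}

test_that("fire transforms are the documented element-wise maps", {
  expect_equal(transform_fire(series_of(c(0, 0, 0)), "log1p")$value,
               c(0, 0, 0))
  expect_equal(transform_fire(series_of(c(3, 3)), "log1p")$value[1],
               1.3862944, tolerance = 1e-7)
  expect_equal(transform_fire(series_of(c(4, 9)), "sqrt")$value, c(2, 3))
  expect_error(transform_fire(series_of(c(-1, 2)), "sqrt"),
               class = "borealfire_invalid")
})

test_that("standardization gives z-scores and is idempotent and affine-invariant", {
  z <- standardize(series_of(c(1, 2, 3)))
  expect_equal(z$value, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(mean(z$value), 0, tolerance = 1e-10)
  expect_equal(sd(z$value), 1, tolerance = 1e-10)

  x <- series_of(rnorm(50))
  z1 <- standardize(x)$value
  expect_equal(standardize(standardize(x))$value, z1, tolerance = 1e-10)
  shifted <- series_of(3.2 * x$value - 7)
  expect_equal(standardize(shifted)$value, z1, tolerance = 1e-10)

  expect_error(standardize(series_of(rep(2, 10))),
               class = "borealfire_degenerate")
})

test_that("binning aggregates left-closed right-open intervals", {
  s <- proxy_series(0:399, rep(1, 400))
  b <- bin_series(s, 200, "mean")
  expect_equal(b$time, c(0, 200))
  expect_equal(b$value, c(1, 1))

  s2 <- proxy_series(0:9, 0:9)
  expect_equal(bin_series(s2, 5, "mean")$value, c(2, 7))
  expect_equal(bin_series(proxy_series(0:9, rep(1, 10)), 5, "sum")$value,
               c(5, 5))

  # sum over full bins conserves the series total
  s3 <- proxy_series(0:99, runif(100))
  expect_equal(sum(bin_series(s3, 10, "sum")$value), sum(s3$value),
               tolerance = 1e-12)

  expect_error(bin_series(s2, -5), class = "borealfire_invalid")
  expect_error(bin_series(s2, 0.5), class = "borealfire_invalid")
})

test_that("compositing standardizes, bins and averages across sites", {
  set.seed(1)
  a <- proxy_series(0:199, rnorm(200))
  single <- composite(list(a), 50)
  direct <- bin_series(standardize(a), 50, "mean")
  expect_equal(single$value, direct$value[!is.na(direct$value)],
               tolerance = 1e-12)
  expect_true(all(single$n_sites == 1))

  dup <- composite(list(a, a), 50)
  expect_equal(dup$value, single$value, tolerance = 1e-12)
  expect_true(all(dup$n_sites == 2))

  # affine transforms of one signal composite to the standardized signal
  b <- proxy_series(a$time, 5 - 2 * a$value)
  aff <- composite(list(a, proxy_series(a$time, 2 * a$value + 3)), 50)
  expect_equal(aff$value, single$value, tolerance = 1e-12)

  # permutation invariance over the site list
  c1 <- composite(list(a, b), 50)
  c2 <- composite(list(b, a), 50)
  expect_equal(c1$value, c2$value, tolerance = 1e-12)
})

test_that("linear detrending leaves residuals orthogonal to time", {
  t <- 1:60
  lin <- proxy_series(t, 2.5 * t - 40)
  expect_equal(detrend_linear(lin)$value, rep(0, 60), tolerance = 1e-10)

  # construct residuals orthogonal to [1, time], then recover them
  set.seed(2)
  raw <- rnorm(60)
  fit <- lm(raw ~ t)
  resid <- unname(raw - fitted(fit))
  s <- proxy_series(t, 1.2 * t + 3 + resid)
  d <- detrend_linear(s)
  expect_equal(d$value, resid, tolerance = 1e-8)
  expect_equal(mean(d$value), 0, tolerance = 1e-8)
  expect_equal(sum(d$value * t), 0, tolerance = 1e-6)

  expect_equal(detrend_linear(d)$value, d$value, tolerance = 1e-10)
  expect_error(detrend_linear(proxy_series(1:2, 1:2)),
               class = "borealfire_degenerate")
})

test_that("moving cumulative sums cover the record in stepped windows", {
  s <- proxy_series(1901:2050, rep(1, 150))
  mc <- moving_cumulative(s, window = 100, step = 10)
  expect_equal(nrow(mc), 6)
  expect_true(all(mc$value == 100))
  expect_equal(mc$time[1], 1901)

  spike <- proxy_series(1:150, c(rep(0, 74), 500, rep(0, 75)))
  ms <- moving_cumulative(spike, window = 50, step = 10)
  covered <- ms$time <= 75 & ms$time + 49 >= 75
  expect_true(all(ms$value[covered] == 500))
  expect_true(all(ms$value[!covered] == 0))

  expect_error(moving_cumulative(proxy_series(1:50, rep(1, 50)), 100),
               class = "borealfire_invalid")
})

test_that("charcoal preparation is Box-Cox + z-score + composite", {
  set.seed(3)
  t <- seq(0, 4000, by = 20)
  f <- abs(sin(t / 300)) + 0.1
  s1 <- proxy_series(t, f + rnorm(length(t), 0, 0.02))

  # lambda = 1 is affine, so the chain reduces to the plain composite
  plain <- composite(list(s1), 200)
  bc1 <- charcoal_prepare(list(s1), bin_width = 200, lambda = 1)
  expect_equal(bc1$value, plain$value, tolerance = 1e-10)

  # scale invariance at lambda = 0 (log): a rescaled copy adds nothing
  s2 <- proxy_series(t, 7.5 * s1$value)
  one <- charcoal_prepare(list(s1), bin_width = 200, lambda = 0)
  two <- charcoal_prepare(list(s1, s2), bin_width = 200, lambda = 0)
  expect_equal(two$value, one$value, tolerance = 1e-10)

  expect_error(charcoal_prepare(list(proxy_series(t, rep(2, length(t))))),
               class = "borealfire_degenerate")
})
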