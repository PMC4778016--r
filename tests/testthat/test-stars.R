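test_that("sigma_l pools window variances", {
  expect_equal(sigma_l(rep(4, 50), 10), 0)

  x <- withr::with_seed(1, rnorm(30))
  expect_equal(sigma_l(x, 30), sd(x), tolerance = 1e-12)

  s_hat <- mean(vapply(1:20, function(s) {
    sigma_l(withr::with_seed(s, rnorm(5000)), 100)
  }, numeric(1)))
  expect_lt(abs(s_hat - 1), 0.05)

  expect_error(sigma_l(rnorm(10), 20), class = "borealfire_invalid")
})

test_that("threshold difference matches the two-sample t quantile", {
  expect_equal(threshold_diff(10, 0.1, 0), 0)
  # t_crit(0.1, 18 df) = 1.73406; diff = t * sqrt(2/10)
  expect_equal(threshold_diff(10, 0.1, 1), 0.77554, tolerance = 1e-4)
  expect_equal(threshold_diff(10, 0.1, 1),
               qt(0.95, 18) * sqrt(2 / 10), tolerance = 1e-12)
  d <- vapply(c(10, 20, 50, 100, 400), threshold_diff,
              numeric(1), alpha = 0.1, sigma_l = 1)
  expect_true(all(diff(d) < 0))
})

test_that("Huber weights bound outlier influence", {
  expect_equal(huber_weight(0.5, 1), 1)
  expect_equal(huber_weight(-0.5, 1), 1)
  expect_equal(huber_weight(2, 1), 0.5)
  expect_equal(huber_weight(-4, 2), 0.5)
  expect_error(huber_weight(1, 0), class = "borealfire_invalid")

  # symmetric data: weighted mean equals the unweighted mean
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(borealfire:::huber_mean(x, 1, 1), mean(x), tolerance = 1e-10)
})

test_that("red-noise prewhitening recovers the lag-1 coefficient", {
  pw0 <- prewhiten_ar1(gen_ar1_series(2000, ar1 = 0, seed = 1),
                       cutoff_l = 100)
  expect_lt(abs(pw0$ar1_hat), 0.05)

  s <- gen_ar1_series(5000, ar1 = 0.6, seed = 2)
  pw <- prewhiten_ar1(s, cutoff_l = 100)
  expect_lt(abs(pw$ar1_hat - 0.6), 0.07)
  y <- pw$series$value
  expect_lt(abs(cor(y[-1], y[-length(y)])), 0.07)
  expect_equal(nrow(pw$series), 4999)

  expect_error(prewhiten_ar1(proxy_series(1:5, rnorm(5))),
               class = "borealfire_degenerate")
})

test_that("regime detection finds planted steps and nothing in constants", {
  flat <- proxy_series(1:300, rep(2.5, 300))
  fit0 <- detect_regimes(flat, cutoff_l = 50)
  expect_length(fit0$change_points, 0)
  expect_equal(fit0$regime_means, 2.5)

  seg <- data.frame(length = c(250, 250), mean = c(0, 2))
  hits <- vapply(1:10, function(s) {
    srs <- gen_regime_series(seg, ar1 = 0.3, seed = s)
    fit <- detect_regimes(srs, cutoff_l = 100)
    cps <- fit$change_points[!fit$provisional]
    length(cps) > 0 && min(abs(cps - 251)) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(detect_regimes(proxy_series(1:50, rnorm(50)), cutoff_l = 100),
               class = "borealfire_invalid")
})

test_that("segmentation is scale- and shift-equivariant with positive RSI", {
  seg <- data.frame(length = c(150, 150), mean = c(0, 1.5))
  srs <- gen_regime_series(seg, ar1 = 0.2, seed = 11)
  fit <- detect_regimes(srs, cutoff_l = 60)
  expect_true(all(fit$rsi > 0))

  scaled <- proxy_series(srs$time, srs$value * 3.7)
  shifted <- proxy_series(srs$time, srs$value + 42)
  expect_equal(detect_regimes(scaled, cutoff_l = 60)$change_points,
               fit$change_points)
  expect_equal(detect_regimes(shifted, cutoff_l = 60)$change_points,
               fit$change_points)

  reg <- tidy(fit)
  expect_equal(nrow(reg), length(fit$change_points) + 1)
})

test_that("confirm/reject decisions match the brute-force RSI oracle", {
  l <- 10
  for (seed in 1:6) {
    for (delta_fac in c(0.4, 0.8, 1.3, 2, 4)) {
      # scale the step relative to the detection threshold of a series
      # with this noise level
      base <- make_step_series(20, 30, 1, 0.3, seed)
      dif0 <- threshold_diff(l, 0.1, sigma_l(base$value, l))
      s <- make_step_series(20, 30, delta_fac * dif0, 0.3, seed)
      oracle <- oracle_stars_decision(s$value, l)
      fit <- detect_regimes(s, cutoff_l = l)
      detected <- any(!fit$provisional)
      expect_identical(detected, oracle$confirmed,
                       label = sprintf("seed %d, delta factor %.1f",
                                       seed, delta_fac))
      if (oracle$confirmed) {
        expect_equal(fit$rsi[1], oracle$rsi, tolerance = 1e-10)
      }
    }
  }
})

test_that("infinite Huber parameter reduces regime means to plain means", {
  seg <- data.frame(length = c(100, 100), mean = c(0, 3))
  srs <- gen_regime_series(seg, ar1 = 0, seed = 21)
  fit <- detect_regimes(srs, cutoff_l = 50, huber_h = Inf)
  reg <- tidy(fit)
  for (k in seq_len(nrow(reg))) {
    idx <- srs$time >= reg$start[k] & srs$time <= reg$end[k]
    expect_equal(reg$mean[k], mean(srs$value[idx]), tolerance = 1e-10)
  }
})
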