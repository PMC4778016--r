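test_that("binomial pmf matches enumeration and factorial oracles", {
  expect_equal(binomial_pmf(10, 0, 0), 1)
  expect_equal(binomial_pmf(10, 10, 1), 1)
  expect_equal(binomial_pmf(4, 2, 0.5), 0.375, tolerance = 1e-12)
  expect_equal(binomial_pmf(10, 5, 0.1), factorial_pmf(10, 5, 0.1),
               tolerance = 1e-12)
  expect_equal(binomial_pmf(10, 5, 0.1), 1.4880348e-3, tolerance = 1e-7)

  for (N in c(3, 7, 12)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (X in 0:N) {
        expect_equal(binomial_pmf(N, X, p), enumerate_pmf(N, X, p),
                     tolerance = 1e-12)
      }
    }
  }

  # independent library cross-check on larger N
  expect_equal(binomial_pmf(2000, 0:2000, 0.013),
               dbinom(0:2000, 2000, 0.013), tolerance = 1e-12)

  expect_error(binomial_pmf(5, 6, 0.5), class = "borealfire_invalid")
  expect_error(binomial_pmf(5, 2, 1.5), class = "borealfire_invalid")
})

test_that("binomial pmf sums to one and its tail is monotone", {
  for (N in c(1, 17, 250, 1000)) {
    expect_equal(sum(binomial_pmf(N, 0:N, 0.03)), 1, tolerance = 1e-12)
  }
  tails <- vapply(0:20, function(x) borealfire:::binomial_tail(20, x, 0.1),
                  numeric(1))
  expect_true(all(diff(tails) <= 1e-15))
  expect_equal(tails[1], 1)
})

test_that("the burn probability is the pooled recording ratio", {
  m <- gen_site_burn_matrix(10, 4, 1, seed = 1)
  expect_equal(estimate_p(m)$p, 1)

  df <- tibble::tibble(
    year = rep(1:10, each = 2),
    site = rep(c("a", "b"), 10),
    burned = rep(c(TRUE, FALSE), 10),
    recording = TRUE
  )
  expect_equal(estimate_p(df)$p, 0.5)

  # non-recording padding does not change the estimate
  pad <- tibble::tibble(year = 1:10, site = "c", burned = FALSE,
                        recording = FALSE)
  expect_equal(estimate_p(dplyr::bind_rows(df, pad))$p, 0.5)

  none <- tibble::tibble(year = 1, site = "a", burned = FALSE,
                         recording = FALSE)
  expect_error(estimate_p(none), class = "borealfire_degenerate")
})

test_that("LFY detection flags binomially surprising years", {
  quiet <- gen_site_burn_matrix(50, 10, 0, seed = 1)
  # a record with no burns at all has p = 0 and no surprising years
  res0 <- detect_lfy(quiet)
  expect_false(any(res0$is_lfy))
  expect_true(all(res0$tail_prob == 1))

  # an extreme year under a small p is flagged far below alpha
  expect_lt(borealfire:::binomial_tail(20, 8, 0.02), 1e-6)

  m <- gen_site_burn_matrix(300, 20, 0.02, lfy_years = c(60, 150, 240),
                            lfy_p = 0.5, seed = 4)
  res <- detect_lfy(m, alpha = 0.05)
  expect_true(all(c(60, 150, 240) %in% res$year[res$is_lfy]))
  expect_true(all(res$tail_prob[res$is_lfy] <= 0.05))

  # invariance to site ordering
  shuffled <- m[withr::with_seed(9, sample(nrow(m))), ]
  res2 <- detect_lfy(shuffled, alpha = 0.05)
  expect_equal(res2$is_lfy, res$is_lfy)

  # years with no recording site are skipped, not treated as X = 0
  m3 <- dplyr::mutate(m, recording = recording & year != 100,
                      burned = burned & year != 100)
  expect_false(100 %in% detect_lfy(m3)$year)
})

test_that("planted LFYs are recovered with high recall", {
  planted <- c(50, 120, 200, 260, 333, 400, 410, 455, 470, 490)
  stats <- t(vapply(1:10, function(s) {
    m <- gen_site_burn_matrix(500, 20, 0.02, lfy_years = planted,
                              lfy_p = 0.4, seed = 100 + s)
    res <- detect_lfy(m, alpha = 0.05)
    found <- res$year[res$is_lfy]
    c(recall = mean(planted %in% found),
      fp = sum(!(found %in% planted)))
  }, numeric(2)))
  expect_true(all(stats[, "recall"] >= 0.9))
  # false flags stay near the binomial expectation (~3.5 per record)
  expect_lt(mean(stats[, "fp"]), 8)
})

test_that("chi-square contingency test follows the Pearson statistic", {
  even <- chi_square_contingency(c(50, 50), c(0.5, 0.5))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  lop <- chi_square_contingency(c(10, 0), c(0.5, 0.5))
  expect_equal(lop$statistic, 10)
  expect_equal(lop$df, 1)

  # trailing classes pooled until expected counts reach 5
  pooled <- chi_square_contingency(c(85, 10, 4, 1), c(0.85, 0.1, 0.04, 0.01))
  expect_equal(pooled$n_classes, 3)

  expect_error(chi_square_contingency(c(1, 2), c(1)),
               class = "borealfire_invalid")
  expect_error(chi_square_contingency(c(1, 2), c(0.6, 0.6)),
               class = "borealfire_invalid")
})
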