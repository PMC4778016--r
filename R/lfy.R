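#' Binomial probability of X burned sites among N recording sites
#'
#' Probability mass `C(N, X) p^X (1 - p)^(N - X)` of observing exactly
#' `X` burned areas in a year when each of `N` recording areas burns
#' independently with probability `p`.  Evaluated in log space so it is
#' stable for records of thousands of sites.
#'
#' @param N Number of recording areas (non-negative integer).
#' @param X Number of burned areas, `0 <= X <= N`; may be a vector.
#' @param p Per-area annual burn probability.
#' @return Probability (vectorized over `X`).
#' @export
binomial_pmf <- function(N, X, p) {
  N <- check_count(N, "N", lower = 0L)
  check_prob(p, "p")
  X <- as.integer(X)
  if (any(X < 0L) || any(X > N)) stop_invalid("`X` must satisfy 0 <= X <= N")
  if (p == 0) return(as.numeric(X == 0L))
  if (p == 1) return(as.numeric(X == N))
  exp(lchoose(N, X) + X * log(p) + (N - X) * log1p(-p))
}

# upper-tail P[count >= X]; exact sum of the pmf
binomial_tail <- function(N, X, p) {
  pmf <- binomial_pmf(N, 0:N, p)
  tail_all <- rev(cumsum(rev(pmf)))
  tail_all <- pmin(tail_all, 1)
  tail_all[X + 1L]
}

#' Estimate the annual per-area burn probability
#'
#' Pools the whole record (optionally a year range): `p` is the fraction
#' of recording site-years that burned.
#'
#' @param data A [site_burn_matrix()] or compatible data frame.
#' @param years Optional year range `c(first, last)` restricting the
#'   estimate to a specific period.
#' @return A `binomial_fire_model` list with elements `p`, `q = 1 - p`,
#'   `n_burned`, `n_recording`.
#' @export
estimate_p <- function(data, years = NULL) {
  data <- as_site_burn_matrix(data)
  if (!is.null(years)) {
    data <- dplyr::filter(data, .data$year >= years[1], .data$year <= years[2])
  }
  n_rec <- sum(data$recording)
  if (n_rec == 0L) stop_degenerate("no recording site-years in the record")
  n_burn <- sum(data$burned)
  structure(
    list(p = n_burn / n_rec, q = 1 - n_burn / n_rec,
         n_burned = n_burn, n_recording = n_rec),
    class = "binomial_fire_model"
  )
}

#' @export
print.binomial_fire_model <- function(x, ...) {
  cat(sprintf("# binomial fire model: p = %.5f (%d / %d site-years)\n",
              x$p, x$n_burned, x$n_recording))
  invisible(x)
}

#' Detect large fire years by binomial contingency analysis
#'
#' For each year the record gives `N` recording areas and `X` burned
#' areas.  Under the null that every area burns independently with
#' probability `p`, the upper-tail probability `P[count >= X]` measures
#' how surprising the year is; years with tail probability at most
#' `alpha` that also burned at least `min_fraction` of recording sites
#' are flagged as large fire years (LFYs).  The record-wide fit of the
#' binomial null is summarized with a Pearson chi-square test of the
#' observed yearly burn-count frequencies against expectation.
#'
#' @param data A [site_burn_matrix()] or compatible data frame.
#' @param alpha Flagging level for the binomial tail probability.
#' @param min_fraction Minimum fraction of recording sites burned
#'   (synchronicity condition); 0 disables it.
#' @param model Optional [estimate_p()] result; estimated from `data`
#'   when omitted.
#' @return An `lfy_result`: a tibble with per-year columns `year`, `N`,
#'   `X`, `fraction_burned`, `tail_prob`, `is_lfy` (years with `N = 0`
#'   are skipped), carrying the model and the chi-square summary as
#'   attributes.  See [glance.lfy_result()].
#' @examples
#' m <- gen_site_burn_matrix(200, 20, 0.02, lfy_years = c(50, 120),
#'                           lfy_p = 0.5, seed = 1)
#' res <- detect_lfy(m)
#' dplyr::filter(res, is_lfy)
#' @export
detect_lfy <- function(data, alpha = 0.05, min_fraction = 0, model = NULL) {
  data <- as_site_burn_matrix(data)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  check_prob(min_fraction, "min_fraction")
  counts <- burn_counts(data)
  counts <- dplyr::filter(counts, .data$N > 0L)
  if (nrow(counts) == 0L) stop_degenerate("record has no recording years")
  model <- model %||% estimate_p(data)
  p <- model$p

  tails <- vapply(seq_len(nrow(counts)), function(i) {
    binomial_tail(counts$N[i], counts$X[i], p)
  }, numeric(1))
  out <- tibble::tibble(
    year = counts$year,
    N = counts$N,
    X = counts$X,
    fraction_burned = counts$X / counts$N,
    tail_prob = tails,
    is_lfy = tails <= alpha & (counts$X / counts$N) >= min_fraction & counts$X > 0L
  )

  chisq <- lfy_chi_square(counts, p)
  attr(out, "model") <- model
  attr(out, "alpha") <- alpha
  attr(out, "min_fraction") <- min_fraction
  attr(out, "chi_square") <- chisq
  class(out) <- c("lfy_result", class(out))
  out
}

# record-wide goodness of fit: observed frequencies of yearly burn counts
# vs the binomial expectation (mixture over the years' N when N varies)
lfy_chi_square <- function(counts, p) {
  max_n <- max(counts$N)
  classes <- 0:max_n
  obs <- tabulate(counts$X + 1L, nbins = max_n + 1L)
  probs <- rowMeans(vapply(seq_len(nrow(counts)), function(i) {
    c(binomial_pmf(counts$N[i], 0:counts$N[i], p),
      rep(0, max_n - counts$N[i]))
  }, numeric(max_n + 1L)))
  chi_square_contingency(obs, probs, p_estimated = TRUE)
}

#' Chi-square test of observed burn-count frequencies
#'
#' Pearson chi-square comparison of observed count-class frequencies
#' against theoretical class probabilities.  Trailing classes are pooled
#' until every expected count is at least 5 (Cochran's rule).  Degrees of
#' freedom are `classes - 1`, minus one more when the binomial `p` was
#' estimated from the data.
#'
#' @param observed Integer vector of observed frequencies per count
#'   class (starting at count 0).
#' @param expected_probs Probability vector of the same length, summing
#'   to 1.
#' @param p_estimated Was the class distribution's parameter estimated
#'   from the same data?
#' @return A one-row tibble with `statistic`, `df`, `p_value` and
#'   `n_classes` (after pooling).
#' @export
chi_square_contingency <- function(observed, expected_probs,
                                   p_estimated = FALSE) {
  if (length(observed) != length(expected_probs)) {
    stop_invalid("`observed` and `expected_probs` must have equal length")
  }
  if (abs(sum(expected_probs) - 1) > 1e-8) {
    stop_invalid("`expected_probs` must sum to 1")
  }
  n <- sum(observed)
  expected <- n * expected_probs
  # pool trailing classes until expected >= 5
  k <- length(expected)
  while (k > 2L && expected[k] < 5) {
    expected[k - 1L] <- expected[k - 1L] + expected[k]
    observed[k - 1L] <- observed[k - 1L] + observed[k]
    expected <- expected[-k]
    observed <- observed[-k]
    k <- k - 1L
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 1L - as.integer(p_estimated)
  p <- if (df >= 1L) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  tibble::tibble(statistic = stat, df = df, p_value = p, n_classes = k)
}

#' @describeIn detect_lfy per-year tibble of diagnostics.
#' @param x An `lfy_result`.
#' @param ... Unused.
#' @export
tidy.lfy_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lfy_result")
  attr(out, "model") <- attr(out, "alpha") <- NULL
  attr(out, "min_fraction") <- attr(out, "chi_square") <- NULL
  out
}

#' One-row summary of an LFY analysis
#'
#' @param x An `lfy_result` from [detect_lfy()].
#' @param ... Unused.
#' @return Tibble with the estimated `p`, the number of flagged LFYs,
#'   and the record-wide chi-square statistic, df and p-value.
#' @export
glance.lfy_result <- function(x, ...) {
  cs <- attr(x, "chi_square")
  tibble::tibble(
    p_hat = attr(x, "model")$p,
    n_years = nrow(x),
    n_lfy = sum(x$is_lfy),
    alpha = attr(x, "alpha"),
    min_fraction = attr(x, "min_fraction"),
    chi_square_stat = cs$statistic,
    chi_square_df = cs$df,
    chi_square_p = cs$p_value
  )
}
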