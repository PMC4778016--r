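# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: enumeration, direct factorial formulas,
# and a plain transcription of the sequential confirmation rule.

# binomial pmf by explicit enumeration of all 2^N site outcomes
enumerate_pmf <- function(N, X, p) {
  outcomes <- expand.grid(rep(list(c(0, 1)), N))
  counts <- rowSums(outcomes)
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(probs[counts == X])
}

# binomial pmf by direct factorial evaluation
factorial_pmf <- function(N, X, p) {
  (factorial(N) / (factorial(X) * factorial(N - X))) *
    p^X * (1 - p)^(N - X)
}

# clean-room transcription of the sequential confirmation rule, up to
# and including the first fully-confirmed shift: window variances and
# Huber means computed with plain loops, RSI accumulated explicitly.
# Returns whether any full-window shift is confirmed and its RSI.
oracle_stars_decision <- function(x, l, alpha = 0.1, h = 1) {
  n <- length(x)
  vars <- vapply(seq_len(n - l + 1), function(i) var(x[i:(i + l - 1)]),
                 numeric(1))
  sig <- sqrt(mean(vars))
  dif <- qt(1 - alpha / 2, df = 2 * l - 2) * sqrt(2 * sig^2 / l)
  hmean <- function(v) {
    mu <- mean(v)
    repeat {
      w <- pmin(1, h / pmax(abs((v - mu) / sig), 1e-300))
      mu_new <- sum(w * v) / sum(w)
      if (abs(mu_new - mu) < 1e-10) return(mu_new)
      mu <- mu_new
    }
  }
  regime_mean <- function(from, upto) {
    hmean(x[from:max(upto, min(from + l - 1, n))])
  }
  rs <- 1
  mu <- regime_mean(rs, rs)
  i <- l + 1
  while (i <= n) {
    if (abs(x[i] - mu) > dif) {
      dir <- sign(x[i] - mu)
      level <- mu + dir * dif
      jmax <- min(i + l - 1, n)
      rsi <- 0
      ok <- TRUE
      for (j in i:jmax) {
        z <- (x[j] - level) / sig
        rsi <- rsi + dir * min(1, h / abs(z)) * z / l
        if (rsi < 0) {
          ok <- FALSE
          break
        }
      }
      if (ok && jmax == i + l - 1) {
        return(list(confirmed = TRUE, candidate = i, rsi = rsi))
      }
      if (ok) return(list(confirmed = FALSE, candidate = i))  # truncated
      mu <- regime_mean(rs, i)
    } else {
      mu <- regime_mean(rs, i)
    }
    i <- i + 1
  }
  list(confirmed = FALSE, candidate = NULL)
}

# step series with an exactly constant pre-segment (so the oracle's
# regime mean is unambiguous) and a noisy post-segment
make_step_series <- function(n_pre, n_post, delta, noise_sd, seed) {
  noise <- withr::with_seed(seed, rnorm(n_post, 0, noise_sd))
  proxy_series(seq_len(n_pre + n_post),
               c(rep(0, n_pre), delta + noise))
}
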