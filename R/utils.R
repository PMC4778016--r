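#' @importFrom rlang abort %||% .data
#' @importFrom stats var sd cor qt pt pchisq quantile median coef lm rnorm runif
#' @importFrom utils head tail
NULL

stop_invalid <- function(msg, ...) {
  abort(msg, class = "borealfire_invalid", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "borealfire_degenerate", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "borealfire_format", ...)
}

# scalar checks used throughout the user-facing surface
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  x
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_invalid(sprintf("`%s` must be an integer", name))
  as.integer(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# lag-1 sample autocorrelation (Pearson on consecutive pairs)
lag1_cor <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  if (sd(x[-n]) == 0 || sd(x[-1]) == 0) return(NA_real_)
  cor(x[-n], x[-1])
}
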