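#' Build a proxy time series
#'
#' A proxy series is the package's basic container for any timestamped
#' scalar record: annually burned area, tree-ring temperature
#' reconstructions, SST, ice-rafted debris, charcoal influx.  It is a
#' tibble with columns `time` (calendar year AD, strictly increasing) and
#' `value`, carrying the nominal resolution (years per step) and a label
#' as attributes.  All series functions accept any data frame with
#' `time`/`value` columns and return a `proxy_series` tibble, so calls
#' chain with the pipe.
#'
#' @param time Numeric vector of calendar years AD, strictly increasing.
#' @param value Numeric vector, same length as `time`.
#' @param resolution Years per step; inferred from the median time step
#'   when omitted.
#' @param label Short description carried through transformations.
#' @return A `proxy_series` tibble with columns `time` and `value`.
#' @examples
#' proxy_series(2001:2010, rnorm(10), label = "burned area")
#' @export
proxy_series <- function(time, value, resolution = NULL, label = "series") {
  if (!is.numeric(time) || !is.numeric(value)) {
    stop_invalid("`time` and `value` must be numeric")
  }
  if (length(time) != length(value)) {
    stop_invalid("`time` and `value` must have equal length")
  }
  if (anyNA(time)) stop_invalid("`time` must not contain missing values")
  if (is.unsorted(time, strictly = TRUE)) {
    stop_invalid("`time` must be strictly increasing")
  }
  if (is.null(resolution)) {
    resolution <- if (length(time) > 1L) median(diff(time)) else 1
  }
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_invalid("`resolution` must be a positive number")
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  attr(out, "resolution") <- as.numeric(resolution)
  attr(out, "label") <- as.character(label)
  class(out) <- c("proxy_series", class(out))
  out
}

#' Coerce a data frame to a proxy series
#'
#' @param x A data frame with numeric `time` and `value` columns (rows in
#'   any order), or an existing `proxy_series`.
#' @param ... Passed to [proxy_series()] (`resolution`, `label`).
#' @return A `proxy_series` tibble.
#' @export
as_proxy_series <- function(x, ...) {
  if (inherits(x, "proxy_series")) return(x)
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x))) {
    stop_invalid("expected a data frame with `time` and `value` columns")
  }
  ord <- order(x$time)
  dots <- list(...)
  res <- dots$resolution %||% attr(x, "resolution", exact = TRUE)
  lab <- dots$label %||% attr(x, "label", exact = TRUE) %||% "series"
  proxy_series(x$time[ord], x$value[ord], resolution = res, label = lab)
}

series_resolution <- function(x) {
  attr(x, "resolution", exact = TRUE) %||%
    (if (nrow(x) > 1L) median(diff(x$time)) else 1)
}

series_label <- function(x) attr(x, "label", exact = TRUE) %||% "series"

#' @export
print.proxy_series <- function(x, ...) {
  cat(sprintf("# proxy series '%s': %d points, resolution %g yr\n",
              series_label(x), nrow(x), series_resolution(x)))
  NextMethod()
}
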