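#' Build a gridded climate field
#'
#' Container for monthly or annual lat/lon fields (SST, 500 hPa heights,
#' PDSI).  Values are stored as a `time x lat x lon` array; the time axis
#' is a `year` vector plus, for monthly fields, a parallel `month`
#' vector.  Use [tidy()][generics::tidy] to get the long tibble view.
#'
#' @param values Numeric array of dim `(n_time, n_lat, n_lon)`.
#' @param lat Latitudes in degrees, strictly ascending after
#'   normalization.
#' @param lon Longitudes in degrees; values in `[0, 360]` are wrapped to
#'   `[-180, 180]`.
#' @param year Integer vector of length `n_time`.
#' @param month Optional integer vector (1-12) of length `n_time`;
#'   omit (`NULL`) for annual fields.
#' @param units Units string carried as metadata.
#' @return A `gridded_field` object.
#' @export
gridded_field <- function(values, lat, lon, year, month = NULL, units = "") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_invalid("`values` must be a 3-d array (time x lat x lon)")
  }
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  year <- as.integer(year)
  d <- dim(values)
  if (d[1] != length(year) || d[2] != length(lat) || d[3] != length(lon)) {
    stop_invalid("array dimensions must match time, lat and lon lengths")
  }
  if (anyDuplicated(lat) || anyDuplicated(lon)) {
    stop_invalid("duplicate lat or lon coordinates")
  }
  # normalize conventions: lon in [-180, 180], lat ascending
  lon <- ifelse(lon > 180, lon - 360, lon)
  if (anyDuplicated(lon)) stop_invalid("duplicate lon coordinates after wrapping")
  if (is.unsorted(lon)) {
    olo <- order(lon)
    lon <- lon[olo]
    values <- values[, , olo, drop = FALSE]
  }
  if (is.unsorted(lat)) {
    ola <- order(lat)
    lat <- lat[ola]
    values <- values[, ola, , drop = FALSE]
  }
  if (!is.null(month)) {
    month <- as.integer(month)
    if (length(month) != d[1] || any(month < 1L | month > 12L)) {
      stop_invalid("`month` must be length n_time with values in 1..12")
    }
    if (anyDuplicated(year * 100L + month)) {
      stop_invalid("duplicate year-month time steps")
    }
  } else if (anyDuplicated(year)) {
    stop_invalid("duplicate years in annual field")
  }
  structure(
    list(values = values, lat = lat, lon = lon, year = year,
         month = month, units = as.character(units)),
    class = "gridded_field"
  )
}

is_monthly <- function(field) !is.null(field$month)

n_cells <- function(field) length(field$lat) * length(field$lon)

# time x cell matrix view (cells vary lat fastest, matching array layout)
field_matrix <- function(field) {
  d <- dim(field$values)
  matrix(field$values, nrow = d[1], ncol = d[2] * d[3])
}

cell_grid <- function(field) {
  expand.grid(lat = field$lat, lon = field$lon, KEEP.OUT.ATTRS = FALSE)
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf(
    "# gridded field: %d x %d cells, %d %s steps (%d-%d)%s\n",
    length(x$lat), length(x$lon), length(x$year),
    if (is_monthly(x)) "monthly" else "annual",
    min(x$year), max(x$year),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' @describeIn gridded_field long tibble view: one row per time step and
#'   grid cell.
#' @param x A `gridded_field`.
#' @param ... Unused.
#' @export
tidy.gridded_field <- function(x, ...) {
  g <- cell_grid(x)
  nt <- length(x$year)
  out <- tibble::tibble(
    year = rep(x$year, times = nrow(g)),
    lat = rep(g$lat, each = nt),
    lon = rep(g$lon, each = nt),
    value = as.vector(field_matrix(x))
  )
  if (is_monthly(x)) {
    out <- tibble::add_column(out, month = rep(x$month, times = nrow(g)),
                              .after = "year")
  }
  out
}
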