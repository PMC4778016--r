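#' Read a proxy series from CSV
#'
#' Expects header columns `time` and `value`; optional columns `label`,
#' `units` and `bp_flag`.  Rows are sorted by time.  When `bp_flag` is
#' truthy, times are taken as calibrated years BP and converted to
#' calendar years AD as `AD = 1950 - BP` (the package's canonical time
#' axis).
#'
#' @param path CSV file path.
#' @return A [proxy_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "value") %in% names(df))) {
    stop_format("series CSV must have columns `time` and `value`")
  }
  if (!is.numeric(df$time) || !is.numeric(df$value)) {
    stop_format("`time` and `value` must be numeric")
  }
  if ("bp_flag" %in% names(df)) {
    bp <- as.logical(df$bp_flag)
    df$time[bp] <- 1950 - df$time[bp]
  }
  if (anyDuplicated(df$time)) stop_format("duplicate timestamps in series")
  lab <- if ("label" %in% names(df)) as.character(df$label[1]) else "series"
  df <- df[order(df$time), ]
  proxy_series(df$time, df$value, label = lab)
}

#' Write a proxy series to CSV
#'
#' @param series Data frame with `time`, `value`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- as_proxy_series(series)
  out <- tibble::tibble(time = series$time, value = series$value,
                        label = series_label(series))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a site-burn record
#'
#' Long CSV with columns `year`, `site`, `burned` (0/1), `recording`
#' (0/1).
#'
#' @param path CSV file path.
#' @return [read_site_burn_matrix()] returns a [site_burn_matrix()].
#' @export
read_site_burn_matrix <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  site_burn_matrix(df)
}

#' @rdname read_site_burn_matrix
#' @param data A [site_burn_matrix()] or compatible data frame.
#' @export
write_site_burn_matrix <- function(data, path) {
  data <- as_site_burn_matrix(data)
  out <- dplyr::mutate(data, burned = as.integer(.data$burned),
                       recording = as.integer(.data$recording))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' Columns `year`, `lat`, `lon`, `value`, plus `month` for monthly
#' fields.  Coordinate conventions are normalized on load (longitudes
#' wrapped to `[-180, 180]`, latitudes ascending).  Write/read round
#' trips preserve values exactly (readr emits shortest round-trip
#' decimal representations).
#'
#' @param path CSV file path.
#' @param units Units string to attach.
#' @return A [gridded_field()].
#' @export
read_field <- function(path, units = "") {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("year", "lat", "lon", "value")
  if (!all(need %in% names(df))) {
    stop_format("field CSV must have columns year, lat, lon, value")
  }
  monthly <- "month" %in% names(df)
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  tkey <- if (monthly) {
    unique(df[order(df$year, df$month), c("year", "month")])
  } else {
    unique(df[order(df$year), "year", drop = FALSE])
  }
  nt <- nrow(tkey)
  if (nrow(df) != nt * length(lat) * length(lon)) {
    stop_format("field CSV is not a complete year x lat x lon grid")
  }
  it <- if (monthly) {
    match(paste(df$year, df$month), paste(tkey$year, tkey$month))
  } else {
    match(df$year, tkey$year)
  }
  arr <- array(NA_real_, dim = c(nt, length(lat), length(lon)))
  arr[cbind(it, match(df$lat, lat), match(df$lon, lon))] <- df$value
  gridded_field(arr, lat = lat, lon = lon, year = tkey$year,
                month = if (monthly) tkey$month else NULL, units = units)
}

#' @rdname read_field
#' @param field A [gridded_field()].
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "gridded_field")) {
    stop_invalid("`field` must be a gridded_field")
  }
  readr::write_csv(tidy(field), path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The configuration is a nested list (stage parameters and seeds); it
#' round-trips losslessly through [yaml::write_yaml()].
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  yaml::read_yaml(path)
}
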