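#' Build a site-burn record
#'
#' Long-format record of a multi-site annual fire history: one row per
#' year and recording site, with logical `burned` and `recording`
#' indicators.  This is the input to [detect_lfy()]; the binomial model
#' counts, per year, the recording sites (N) and the burned sites (X).
#'
#' @param data Data frame with columns `year`, `site`, `burned`,
#'   `recording` (`burned`/`recording` logical or 0/1).
#' @return A `site_burn_matrix` tibble (one row per year x site).
#' @export
site_burn_matrix <- function(data) {
  need <- c("year", "site", "burned", "recording")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop_invalid("expected columns year, site, burned, recording")
  }
  out <- tibble::tibble(
    year = as.integer(data$year),
    site = as.character(data$site),
    burned = as.logical(data$burned),
    recording = as.logical(data$recording)
  )
  if (anyNA(out$burned) || anyNA(out$recording)) {
    stop_invalid("`burned` and `recording` must be logical or 0/1")
  }
  if (any(out$burned & !out$recording)) {
    stop_invalid("a burned site-year must also be recording")
  }
  if (anyDuplicated(out[c("year", "site")])) {
    stop_invalid("duplicate year-site rows")
  }
  out <- dplyr::arrange(out, .data$year, .data$site)
  class(out) <- c("site_burn_matrix", class(out))
  out
}

as_site_burn_matrix <- function(x) {
  if (inherits(x, "site_burn_matrix")) x else site_burn_matrix(x)
}

# per-year counts of recording (N) and burned (X) sites
burn_counts <- function(data) {
  data <- as_site_burn_matrix(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$year),
    N = sum(.data$recording),
    X = sum(.data$burned),
    .groups = "drop"
  )
}
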