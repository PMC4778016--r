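#' Default configuration of the demonstration pipeline
#'
#' Assembles the full analysis chain on synthetic inputs whose
#' statistical structure mirrors the study design: a 500-year,
#' 20-site fire record with rare site burns and ten high-synchrony
#' large fire years placed preferentially in cold periods, an annual
#' temperature series with century-scale cold and warm regimes, and a
#' modern gridded field negatively teleconnected to the fire record in
#' a localized block.
#' All stage seeds derive deterministically from `seed`.
#'
#' @param seed Master integer seed.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  seed <- check_count(seed, "seed", lower = 0L)
  list(
    seeds = list(
      fire = seed + 101L, temperature = seed + 202L,
      field = seed + 303L, boot = seed + 404L, perm = seed + 505L
    ),
    simulate = list(
      n_years = 500L, n_sites = 20L, start_year = 1401L,
      base_p = 0.02, lfy_p = 0.4,
      # large fire years cluster in the cold segments (positions
      # 151-270 and 401-500 below), emulating the studied association
      lfy_positions = c(30L, 160L, 185L, 215L, 240L, 265L, 320L, 420L,
                        450L, 480L),
      temperature = list(
        segments = data.frame(length = c(150L, 120L, 130L, 100L),
                              mean = c(0, -0.8, 0.4, -0.6)),
        ar1 = 0.3, sd = 1
      ),
      field = list(nlat = 20L, nlon = 30L, years = 100L,
                   block_lat = c(6L, 10L), block_lon = c(8L, 14L),
                   coupling = -0.5, noise_sd = 0.9)
    ),
    lfy = list(alpha = 0.05, min_fraction = 0),
    stars = list(cutoff_l = 100L, alpha = 0.1, huber_h = 1),
    bootstrap = list(n_boot = 1000L),
    field = list(alpha = 0.1, n_perm = 199L),
    sea = list(n_events = 5L, n_boot = 500L)
  )
}

write_stage <- function(out_dir, name, df) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Run the full fire-climate analysis pipeline
#'
#' Executes the stages in analysis order -- simulate inputs, condition
#' the fire series, detect large fire years, segment the temperature
#' series into regimes, bootstrap-test LFY clustering in cold regimes,
#' map the index-field teleconnection, and run the superposed epoch
#' analysis -- writing one CSV per stage plus a JSON-lines log recording
#' every seed and parameter.  Reruns with the same configuration are
#' bit-identical.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the stage results and the written
#'   file manifest.
#' @examples
#' \donttest{
#' res <- run_pipeline(default_pipeline_config(1), out_dir = tempfile())
#' glance(res$lfy)
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "pipeline-out") {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config)) stop_invalid("`config` must be a list or YAML path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline-log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_entry <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  manifest <- character(0)
  sim <- config$simulate

  # --- simulate ------------------------------------------------------
  if (is.data.frame(sim$temperature$segments)) {
    segs <- sim$temperature$segments
  } else {
    segs <- as.data.frame(lapply(sim$temperature$segments, unlist))
  }
  fire <- gen_site_burn_matrix(
    sim$n_years, sim$n_sites, sim$base_p,
    lfy_years = sim$lfy_positions, lfy_p = sim$lfy_p,
    seed = config$seeds$fire, start_year = sim$start_year
  )
  temperature <- gen_regime_series(
    segs, ar1 = sim$temperature$ar1, sd = sim$temperature$sd,
    seed = config$seeds$temperature, start_year = sim$start_year,
    label = "summer temperature"
  )
  log_entry("simulate", seed_fire = config$seeds$fire,
            seed_temperature = config$seeds$temperature,
            n_years = sim$n_years, n_sites = sim$n_sites,
            base_p = sim$base_p, lfy_p = sim$lfy_p)
  manifest <- c(manifest,
                write_stage(out_dir, "fire_record",
                            as_site_burn_matrix(fire)),
                write_stage(out_dir, "temperature", temperature))

  # --- process: annual fraction burned, smoothed chronology ----------
  counts <- burn_counts(fire)
  burned_frac <- proxy_series(counts$year, counts$X / counts$N,
                              resolution = 1, label = "fraction burned")
  smoothed <- moving_cumulative(burned_frac, window = 100, step = 10)
  log_entry("process", window = 100, step = 10)
  manifest <- c(manifest, write_stage(out_dir, "fire_smoothed", smoothed))

  # --- lfy -----------------------------------------------------------
  lfy_res <- detect_lfy(fire, alpha = config$lfy$alpha,
                        min_fraction = config$lfy$min_fraction)
  log_entry("lfy", alpha = config$lfy$alpha,
            min_fraction = config$lfy$min_fraction,
            p_hat = attr(lfy_res, "model")$p,
            n_lfy = sum(lfy_res$is_lfy))
  manifest <- c(manifest, write_stage(out_dir, "lfy", tidy(lfy_res)))

  # --- regimes on the temperature series -----------------------------
  seg <- detect_regimes(detrend_linear(temperature),
                        cutoff_l = config$stars$cutoff_l,
                        alpha = config$stars$alpha,
                        huber_h = config$stars$huber_h)
  log_entry("regimes", cutoff_l = config$stars$cutoff_l,
            alpha = config$stars$alpha,
            n_shifts = sum(!seg$provisional))
  manifest <- c(manifest, write_stage(out_dir, "regimes", tidy(seg)))

  # --- bootstrap association test ------------------------------------
  labels <- label_years(seg)
  lfy_years <- lfy_res$year[lfy_res$is_lfy]
  boot <- NULL
  if (length(lfy_years) >= 1L) {
    boot <- bootstrap_lfy_test(lfy_years, labels,
                               n_boot = config$bootstrap$n_boot,
                               seed = config$seeds$boot)
    log_entry("boottest", n_boot = config$bootstrap$n_boot,
              seed = config$seeds$boot, p_value = boot$p_value,
              observed_diff = boot$observed_diff)
    manifest <- c(manifest, write_stage(out_dir, "boottest", glance(boot)))
  }

  # --- teleconnection field statistics -------------------------------
  fld <- sim$field
  modern_years <- utils::tail(counts$year, fld$years)
  index <- transform_fire(
    proxy_series(modern_years,
                 (counts$X / counts$N)[match(modern_years, counts$year)],
                 resolution = 1, label = "modern fire index"),
    "sqrt"
  )
  field <- gen_teleconnected_field(
    index, fld$nlat, fld$nlon,
    block_lat = unlist(fld$block_lat), block_lon = unlist(fld$block_lon),
    coupling = fld$coupling, noise_sd = fld$noise_sd,
    seed = config$seeds$field
  )
  cmap <- correlation_map(index, field, alpha = config$field$alpha,
                          n_perm = config$field$n_perm,
                          seed = config$seeds$perm)
  log_entry("fieldcorr", alpha = config$field$alpha,
            n_perm = config$field$n_perm, seed = config$seeds$perm,
            p_field = cmap$p_field,
            frac_significant = cmap$frac_significant)
  manifest <- c(manifest, write_stage(out_dir, "fieldcorr", tidy(cmap)))

  # --- superposed epoch analysis on the largest modern fire years ----
  modern_frac <- index$value
  top <- order(modern_frac, decreasing = TRUE)[seq_len(config$sea$n_events)]
  event_years <- round(index$time[top])
  sea_res <- sea(field, event_years, n_boot = config$sea$n_boot,
                 seed = config$seeds$boot)
  log_entry("sea", event_years = event_years,
            n_boot = config$sea$n_boot, seed = config$seeds$boot)
  manifest <- c(manifest, write_stage(out_dir, "sea", tidy(sea_res)))

  invisible(list(
    fire = fire, temperature = temperature, smoothed = smoothed,
    lfy = lfy_res, regimes = seg, labels = labels, boottest = boot,
    fieldcorr = cmap, sea = sea_res,
    manifest = manifest, log = log_path
  ))
}
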