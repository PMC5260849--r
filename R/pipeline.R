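stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Chains every stage end to end: simulate ground truth, render counts,
#' build the clear-sky climatology, detect clouds, compute the JJA
#' frequency map and box series, forest/non-forest comparison statistics,
#' wind-conditioned composites, and the breakpoint amplitude fit on the
#' dekadal difference series. Writes all tabular outputs plus a
#' reproducibility manifest (config, seed, package version, output hashes)
#' to `out_dir`.
#'
#' @param config A run configuration: list or YAML path (see
#'   [read_run_config()]). Recognised fields: `grid` (nx, ny, forest,
#'   optional damage/water rectangles as 4-vectors), `start`, `end`,
#'   `months`, `daylight`, `cadence_minutes`, generator parameters
#'   (`p_cloud_base`, `delta_forest_jja`, `cloud_boost_counts`, `noise_sd`,
#'   `wind_displacement_km_per_ms`, `wind_sd`, `klaus_date`,
#'   `klaus_residual_delta`, `missing_rate`), analysis parameters
#'   (`threshold`, `window_w`, `min_samples`, `n_boot`, `wind_edges`,
#'   `season_months`) and `seed`.
#' @param out_dir Output directory (created if needed).
#' @param wind_csv Optional path to a daily wind CSV overriding the
#'   simulated wind.
#' @return Invisibly, a list with the in-memory artifacts (`landcover`,
#'   `truth`, `counts`, `clim`, `mask`, `freq_jja`, `series`, `ttest`,
#'   `intervals`, `significant`, `composite`, `klaus`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, wind_csv = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lc <- stage("landcover", {
    g <- config$grid
    build_landcover(g$nx, g$ny, forest_rect = as_rect(g$forest),
                    damage_rect = if (is.null(g$damage)) NULL else as_rect(g$damage),
                    water_rect = if (is.null(g$water)) NULL else as_rect(g$water))
  })

  wind <- NULL
  if (!is.null(wind_csv))
    wind <- stage("wind", read_wind_csv(wind_csv))

  scfg <- stage("config", sim_config(
    start = config$start, end = config$end, months = config$months,
    daylight = config$daylight, cadence_minutes = config$cadence_minutes,
    p_cloud_base = config$p_cloud_base,
    delta_forest_jja = config$delta_forest_jja,
    cloud_boost_counts = config$cloud_boost_counts,
    noise_sd = config$noise_sd,
    wind_displacement_km_per_ms = config$wind_displacement_km_per_ms,
    wind = wind, wind_sd = config$wind_sd,
    klaus_date = config$klaus_date,
    klaus_residual_delta = config$klaus_residual_delta,
    missing_rate = config$missing_rate, seed = config$seed))

  truth <- stage("simulate", simulate_truth(lc, scfg))
  counts <- stage("render", render_counts(truth, threshold_hint = config$threshold))
  clim <- stage("climatology",
                build_clearsky_climatology(counts, window_w = config$window_w,
                                           min_samples = config$min_samples))
  mask <- stage("detect", detect_clouds(counts, clim, threshold = config$threshold))

  sm <- config$season_months
  freq_jja <- stage("frequency", frequency_map(mask, months = sm))
  fbox <- get_box(lc, "forest")
  nf1 <- get_box(lc, "nonforest_1"); nf2 <- get_box(lc, "nonforest_2")

  series <- stage("series", list(
    forest = box_daily_series(mask, fbox, months = sm),
    nonforest_1 = box_daily_series(mask, nf1, months = sm),
    nonforest_2 = box_daily_series(mask, nf2, months = sm),
    dekadal_diff = dekadal_difference_series(mask, fbox, list(nf1, nf2))))

  ttest <- stage("compare", ttest_two_boxes(series$forest,
                                            rbind(series$nonforest_1,
                                                  series$nonforest_2)))
  fdaily <- stage("compare", box_daily_by_dekad(mask, fbox, months = sm))
  nfdaily <- stage("compare", {
    d1 <- box_daily_by_dekad(mask, nf1, months = sm)
    d2 <- box_daily_by_dekad(mask, nf2, months = sm)
    m <- merge(d1, d2, by = c("date", "bin"), suffixes = c("_1", "_2"))
    data.frame(date = m$date, bin = m$bin,
               value = (m$value_1 + m$value_2) / 2, n = m$n_1 + m$n_2)
  })
  intervals <- stage("compare",
                     bootstrap_percentile_intervals(fdaily, n_boot = config$n_boot,
                                                    seed = config$seed + 1L))
  signif <- stage("compare",
                  significant_bins(fdaily, nfdaily, n_boot = config$n_boot,
                                   seed = config$seed + 2L))

  cls <- stage("composite", classify_days(truth$wind, edges = config$wind_edges))
  composite <- stage("composite",
                     composite_frequency(mask, cls, months = sm,
                                         landcover = lc))

  klaus <- stage("klausfit",
                 amplitude_change(series$dekadal_diff,
                                  breakpoint = config$klaus_date))

  # ---- write artifacts -----------------------------------------------------
  outputs <- character(0)
  wr <- function(fun, obj, name) {
    p <- file.path(out_dir, name)
    fun(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  wr(write_landcover, lc, "landcover.csv")
  wr(write_wind_csv, truth$wind, "wind.csv")
  wr(write_frequency_csv, freq_jja, "frequency_jja.csv")
  wr(write_series_csv, series$forest, "series_forest_daily.csv")
  wr(write_series_csv, series$nonforest_1, "series_nonforest1_daily.csv")
  wr(write_series_csv, series$nonforest_2, "series_nonforest2_daily.csv")
  wr(write_series_csv, series$dekadal_diff, "series_dekadal_diff.csv")
  wr(write_series_csv, intervals, "bootstrap_intervals.csv")
  wr(write_series_csv, signif, "significant_bins.csv")
  fitrep <- list(
    ttest = list(t = ttest$t, df = ttest$df, p = ttest$p, n = ttest$n),
    klaus = list(breakpoint = format(klaus$breakpoint),
                 A_pre = klaus$A_pre, ci_pre = unname(klaus$ci_pre),
                 A_post = klaus$A_post, ci_post = unname(klaus$ci_post),
                 ratio = klaus$ratio),
    composite_levels = lapply(composite$classes, function(cl)
      list(n_days = cl$n_days, level = cl$level, mean_v = cl$mean_v)))
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(fitrep, p, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, p)

  manifest <- list(
    package = "forestcloud",
    version = as.character(utils::packageVersion("forestcloud")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(landcover = lc, truth = truth, counts = counts, clim = clim,
                 mask = mask, freq_jja = freq_jja, series = series,
                 ttest = ttest, intervals = intervals, significant = signif,
                 composite = composite, klaus = klaus, manifest = manifest))
}
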