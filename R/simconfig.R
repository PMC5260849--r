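#' Configuration for the synthetic scene generator
#'
#' Collects every tunable of the synthetic ground-truth generator. Defaults
#' follow the study conditions the pipeline is designed for: 10-bit
#' visible-channel digital counts, a 0.10 summer (JJA) enhancement of cloud
#' occurrence probability over forest, forest/non-forest albedos drawn from
#' 0.11-0.14 / 0.16-0.19, and a storm breakpoint (24 January 2009 by default)
#' after which the enhancement inside the damage zone drops to a small
#' residual.
#'
#' @param start,end Record span (calendar days, inclusive).
#' @param months Optional month filter for the simulated record (e.g. `6:8`
#'   to simulate summer days only); `NULL` keeps all days.
#' @param daylight Half-open UTC hour window, default `c(6, 18)`.
#' @param cadence_minutes Slot cadence, default 15 (must divide 60).
#' @param albedo_forest,albedo_nonforest,albedo_water Surface albedo; a
#'   length-2 range is sampled once per simulation (seeded), a scalar is used
#'   as is.
#' @param clear_base_counts Scale factor converting albedo times the
#'   solar-cycle factor into clear-sky digital counts.
#' @param cloud_boost_counts Additive count brightening of cloudy pixels.
#' @param noise_sd Gaussian count noise standard deviation.
#' @param p_cloud_base Baseline per-slot cloud occurrence probability.
#' @param delta_forest_jja Additional cloud probability over forest pixels in
#'   June-August (0 outside JJA).
#' @param diurnal_lead_hours Hours by which the morning cloud onset over
#'   forest leads the non-forest onset (0 = time-homogeneous occurrence).
#' @param wind_displacement_km_per_ms Downwind shift of the forest
#'   enhancement field, km per (m/s) of daily regional wind.
#' @param wind Optional daily wind `data.frame` (`date`, `u10`, `v10`); when
#'   `NULL`, winds are drawn i.i.d. Normal(0, `wind_sd`) per day.
#' @param wind_sd Standard deviation (m/s) of simulated daily wind components.
#' @param klaus_date Breakpoint date after which the damage-zone enhancement
#'   is reduced (applied only when the land cover has a damage zone).
#' @param klaus_residual_delta Post-breakpoint JJA enhancement inside the
#'   damage zone.
#' @param missing_rate Fraction of count observations replaced by missing
#'   values during rendering.
#' @param seed Integer RNG seed; mandatory.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(start, end,
                       months = NULL,
                       daylight = c(6, 18),
                       cadence_minutes = 15,
                       albedo_forest = c(0.11, 0.14),
                       albedo_nonforest = c(0.16, 0.19),
                       albedo_water = 0.06,
                       clear_base_counts = 600,
                       cloud_boost_counts = 50,
                       noise_sd = 2,
                       p_cloud_base = 0.3,
                       delta_forest_jja = 0.10,
                       diurnal_lead_hours = 0,
                       wind_displacement_km_per_ms = 5,
                       wind = NULL,
                       wind_sd = 2,
                       klaus_date = as.Date("2009-01-24"),
                       klaus_residual_delta = 0.020,
                       missing_rate = 0,
                       seed = NULL) {
  cal <- slot_calendar(start, end, cadence_minutes, daylight, months)
  probs <- c(p_cloud_base = p_cloud_base, delta_forest_jja = delta_forest_jja,
             klaus_residual_delta = klaus_residual_delta,
             missing_rate = missing_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (p_cloud_base + delta_forest_jja > 1)
    stop("p_cloud_base + delta_forest_jja exceeds 1")
  if (clear_base_counts < 0 || clear_base_counts > 1023)
    stop("clear_base_counts must be a 10-bit count level")
  if (cloud_boost_counts < 0 || cloud_boost_counts > 1023)
    stop("cloud_boost_counts must be within the 10-bit range")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  for (a in list(albedo_forest, albedo_nonforest, albedo_water))
    if (!length(a) %in% 1:2 || any(a <= 0 | a >= 1)) stop("invalid albedo")
  if (!is.null(wind)) {
    if (!all(c("date", "u10", "v10") %in% names(wind)))
      stop("wind must have columns date, u10, v10")
    wind$date <- as.Date(wind$date)
  }
  if (is.null(seed)) stop("sim_config requires an integer seed")
  structure(list(calendar = cal,
                 start = cal$start, end = cal$end, months = cal$months,
                 daylight = cal$daylight, cadence_minutes = cal$cadence_minutes,
                 albedo_forest = albedo_forest,
                 albedo_nonforest = albedo_nonforest,
                 albedo_water = albedo_water,
                 clear_base_counts = clear_base_counts,
                 cloud_boost_counts = cloud_boost_counts,
                 noise_sd = noise_sd,
                 p_cloud_base = p_cloud_base,
                 delta_forest_jja = delta_forest_jja,
                 diurnal_lead_hours = diurnal_lead_hours,
                 wind_displacement_km_per_ms = wind_displacement_km_per_ms,
                 wind = wind, wind_sd = wind_sd,
                 klaus_date = as.Date(klaus_date),
                 klaus_residual_delta = klaus_residual_delta,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config %s .. %s, %d-min, p0=%.2f, delta_JJA=%.3f, seed=%d>\n",
              format(x$start), format(x$end), x$cadence_minutes,
              x$p_cloud_base, x$delta_forest_jja, x$seed))
  invisible(x)
}
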