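#' Simulate ground truth for a synthetic scene
#'
#' Draws, under a fixed seed, everything the downstream stages estimate: a
#' per-pixel clear-sky count level for every (dekad, hour) bin, a Bernoulli
#' cloud occurrence flag for every pixel and 15-min slot, and a daily
#' regional 10-m wind record. Cloud occurrence is `p_cloud_base` everywhere,
#' plus `delta_forest_jja` over forest pixels during June-August; the
#' enhancement field is displaced downwind by
#' `wind_displacement_km_per_ms * wind` (rounded to whole pixels) and, after
#' `klaus_date`, is reduced to `klaus_residual_delta` inside the land cover's
#' damage zone.
#'
#' The clear-sky level is `clear_base_counts * albedo` scaled by a smooth
#' solar factor in hour (half-sine over the daylight window) and dekad
#' (annual cosine peaking near the solstice), so darker (forest) pixels have
#' lower clear-sky counts.
#'
#' @param landcover A [build_landcover()] map.
#' @param cfg A [sim_config()].
#' @return An object of class `truth_stack`: `time` (POSIXct), `scheme`
#'   ([bin_scheme()]), `clearsky` (ny x nx x n_bins integer array),
#'   `true_cloud` (ny x nx x nt logical array), `wind` (daily data.frame),
#'   `albedo` (ny x nx matrix), plus the generating `landcover` and `cfg`.
#' @export
simulate_truth <- function(landcover, cfg) {
  stopifnot(inherits(landcover, "landcover"), inherits(cfg, "sim_config"))
  time <- slot_times(cfg$calendar)
  if (length(time) == 0L) stop("empty record: calendar retains no slots")
  meta <- slot_meta(time)
  scheme <- bin_scheme(cfg$daylight)
  ny <- landcover$ny; nx <- landcover$nx; npix <- ny * nx

  with_seed(cfg$seed, {
    draw1 <- function(a) if (length(a) == 2L) stats::runif(1, a[1], a[2]) else a
    alb <- matrix(draw1(cfg$albedo_nonforest), ny, nx)
    alb[landcover$classes == "forest"] <- draw1(cfg$albedo_forest)
    alb[landcover$classes == "water"] <- draw1(cfg$albedo_water)

    days <- calendar_days(cfg$calendar)
    wind <- cfg$wind
    if (is.null(wind)) {
      wind <- data.frame(date = days,
                         u10 = stats::rnorm(length(days), 0, cfg$wind_sd),
                         v10 = stats::rnorm(length(days), 0, cfg$wind_sd))
    } else {
      miss <- !(days %in% wind$date)
      if (any(miss)) stop("supplied wind series does not cover the record")
      wind <- wind[match(days, wind$date), , drop = FALSE]
      rownames(wind) <- NULL
    }

    clearsky <- clearsky_table(alb, cfg, scheme)
    true_cloud <- draw_cloud_truth(landcover, cfg, time, meta, wind)
  })

  structure(list(time = time, scheme = scheme, clearsky = clearsky,
                 true_cloud = true_cloud, wind = wind, albedo = alb,
                 landcover = landcover, cfg = cfg),
            class = "truth_stack")
}

# clear-sky digital counts per pixel per (dekad, hour) bin
clearsky_table <- function(alb, cfg, scheme) {
  d1 <- scheme$daylight[1]; d2 <- scheme$daylight[2]
  f_hour <- 0.15 + 0.85 * sin(pi * (scheme$hours + 0.5 - d1) / (d2 - d1))
  doy_mid <- (seq_len(36L) - 1L) * 10L + 5.5
  f_dekad <- 0.75 + 0.25 * cos(2 * pi * (doy_mid - 172) / 365.25)
  fac <- rep(f_dekad, each = scheme$n_hours) * rep(f_hour, times = 36L)
  vals <- round(outer(c(cfg$clear_base_counts * alb), fac))
  storage.mode(vals) <- "integer"
  vals <- clamp(vals, 0L, 1023L)
  array(vals, dim = c(dim(alb), scheme$n_bins))
}

# Bernoulli cloud truth, day by day (daily wind sets the displacement).
draw_cloud_truth <- function(landcover, cfg, time, meta, wind) {
  ny <- landcover$ny; nx <- landcover$nx; npix <- ny * nx
  nt <- length(time)
  out <- array(FALSE, dim = c(ny, nx, nt))
  forest <- landcover$classes == "forest"
  dmg <- if (!is.null(landcover$damage_zone))
    rect_mask(landcover$damage_zone, ny, nx) else NULL
  day_idx <- match(meta$date, wind$date)
  lead <- cfg$diurnal_lead_hours
  slot_of_day <- split(seq_len(nt), day_idx)

  for (d in seq_along(wind$date)) {
    slots <- slot_of_day[[as.character(d)]]
    if (is.null(slots)) next
    date <- wind$date[d]
    mon <- as.integer(format(date, "%m"))
    enh <- matrix(0, ny, nx)
    if (mon %in% 6:8) {
      enh[forest] <- cfg$delta_forest_jja
      if (!is.null(dmg) && date >= cfg$klaus_date)
        enh[dmg] <- cfg$klaus_residual_delta
      dr <- -round(cfg$wind_displacement_km_per_ms * wind$v10[d] /
                     landcover$pixel_km)
      dc <- round(cfg$wind_displacement_km_per_ms * wind$u10[d] /
                    landcover$pixel_km)
      enh <- shift_matrix(enh, dr, dc)
    }
    if (lead > 0) {
      # morning-onset ramp, advanced by `lead` hours over forest
      for (s in slots) {
        h <- meta$hour[s] + 0.5
        m_nf <- stats::plogis(h - 9)
        m_f <- stats::plogis(h - (9 - lead))
        p <- matrix(cfg$p_cloud_base * m_nf, ny, nx)
        p[forest] <- cfg$p_cloud_base * m_f
        p <- clamp(p + enh, 0, 1)
        out[, , s] <- stats::runif(npix) < p
      }
    } else {
      p <- clamp(cfg$p_cloud_base + enh, 0, 1)
      k <- length(slots)
      out[, , slots] <- stats::runif(npix * k) < as.vector(p)
    }
  }
  out
}

# integer-pixel shift with zero fill; positive dr moves content south (down)
shift_matrix <- function(m, dr, dc) {
  ny <- nrow(m); nx <- ncol(m)
  if (dr == 0 && dc == 0) return(m)
  out <- matrix(0, ny, nx)
  src_r <- seq_len(ny) - dr
  src_c <- seq_len(nx) - dc
  ok_r <- src_r >= 1L & src_r <= ny
  ok_c <- src_c >= 1L & src_c <= nx
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' @export
print.truth_stack <- function(x, ...) {
  cat(sprintf("<truth_stack %d x %d px, %d slots (%s .. %s)>\n",
              dim(x$true_cloud)[1], dim(x$true_cloud)[2], length(x$time),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' Render digital counts from ground truth
#'
#' `count = round(clearsky + cloud_boost * cloud + noise)` clipped to the
#' 10-bit range, with missing values injected at `cfg$missing_rate`. Noise
#' and missingness use a seed derived deterministically from `cfg$seed`.
#'
#' @param truth A [simulate_truth()] result.
#' @param cfg The [sim_config()] used (defaults to `truth$cfg`).
#' @param threshold_hint Detection threshold the stack is destined for; a
#'   warning is raised when `cloud_boost_counts` does not exceed it (clouds
#'   would be undetectable by construction).
#' @return An object of class `count_stack`: `counts` (ny x nx x nt integer
#'   array, `NA` = missing), `time`, `scheme`.
#' @export
render_counts <- function(truth, cfg = truth$cfg, threshold_hint = 10) {
  stopifnot(inherits(truth, "truth_stack"))
  if (cfg$cloud_boost_counts <= threshold_hint)
    warning("cloud_boost_counts does not exceed the detection threshold; ",
            "clouds are undetectable by construction")
  dims <- dim(truth$true_cloud)
  ny <- dims[1]; nx <- dims[2]; nt <- dims[3]; npix <- ny * nx
  bins <- time_bin(truth$time, truth$scheme)$bin
  counts <- array(NA_integer_, dims)
  with_seed(cfg$seed %% 998244353L + 7654321L, {
    for (b in unique(bins)) {
      slots <- which(bins == b)
      k <- length(slots)
      chunk <- as.numeric(truth$clearsky[, , b]) +
        cfg$cloud_boost_counts * as.numeric(truth$true_cloud[, , slots])
      if (cfg$noise_sd > 0)
        chunk <- chunk + stats::rnorm(npix * k, 0, cfg$noise_sd)
      chunk <- as.integer(clamp(round(chunk), 0, 1023))
      if (cfg$missing_rate > 0)
        chunk[stats::runif(npix * k) < cfg$missing_rate] <- NA_integer_
      counts[, , slots] <- chunk
    }
  })
  structure(list(counts = counts, time = truth$time, scheme = truth$scheme),
            class = "count_stack")
}

#' @export
print.count_stack <- function(x, ...) {
  cat(sprintf("<count_stack %d x %d px, %d slots, %.2f%% missing>\n",
              dim(x$counts)[1], dim(x$counts)[2], length(x$time),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' Cloud-mask stack taken directly from the simulation truth
#'
#' Wraps the generator's Bernoulli occurrence flags as a mask stack, the
#' error-free reference against which detected masks are scored.
#'
#' @param truth A [simulate_truth()] result.
#' @return A `cloud_mask` object (flags 0 = clear, 1 = cloud).
#' @export
truth_mask_stack <- function(truth) {
  stopifnot(inherits(truth, "truth_stack"))
  flags <- array(as.integer(truth$true_cloud), dim = dim(truth$true_cloud))
  structure(list(flags = flags, time = truth$time, scheme = truth$scheme,
                 threshold = NA_real_),
            class = "cloud_mask")
}

#' Simulate a dekadal forest-minus-nonforest difference series
#'
#' Generates the 10-day-mean cloud-frequency difference directly at the
#' series level: an annual squared-sine cycle with offset and trend whose
#' amplitude drops from `A_pre` to `A_post` at the breakpoint, plus Gaussian
#' noise. This is the reference process for the breakpoint amplitude fit.
#'
#' @param start_year,end_year Calendar years covered (36 dekads each).
#' @param A_pre,A_post Cycle amplitude before/after the breakpoint
#'   (defaults 0.114 and 0.020).
#' @param breakpoint Breakpoint date (default 2009-01-24).
#' @param c0 Offset; `trend` linear trend per year; `phase` cycle phase in
#'   years (peak at `phase + 0.5` years after the series start).
#' @param noise_sd Gaussian noise SD (default 0.02).
#' @param seed Integer seed.
#' @return `data.frame` with columns `date` (mid-dekad), `year`, `dekad`,
#'   `value`, `segment` (`"pre"`/`"post"`).
#' @export
simulate_dekadal_difference <- function(start_year = 2004, end_year = 2013,
                                        A_pre = 0.114, A_post = 0.020,
                                        breakpoint = as.Date("2009-01-24"),
                                        c0 = 0, trend = 0, phase = 0,
                                        noise_sd = 0.02, seed = NULL) {
  breakpoint <- as.Date(breakpoint)
  grid <- expand.grid(dekad = seq_len(36L), year = start_year:end_year)
  date <- dekad_start(grid$year, grid$dekad) + 4L
  t <- (as.numeric(date) - as.numeric(date[1])) / 365.25
  A <- ifelse(date < breakpoint, A_pre, A_post)
  mu <- c0 + trend * t + A * sin(pi * (t - phase))^2
  value <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  data.frame(date = date, year = grid$year, dekad = grid$dekad,
             value = value,
             segment = ifelse(date < breakpoint, "pre", "post"))
}
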