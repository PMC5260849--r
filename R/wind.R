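#' Classify days by meridional wind speed and direction
#'
#' Each day is assigned one speed class from the meridional (v) component
#' using the edge list (default `c(-1, 1)` m/s, giving classes `v < -1`,
#' `-1 <= v <= 1`, `v > 1`; both default edges belong to the middle class,
#' interior edges of longer lists belong to the lower class) and one of 8
#' direction sectors in the meteorological convention (the direction the
#' wind blows FROM; boundaries belong to the lower sector).
#'
#' @param wind Daily `data.frame` with columns `date`, `u10`, `v10` (m/s).
#' @param edges Increasing numeric vector of meridional speed edges (m/s).
#' @return An object of class `day_classification`: the wind frame with
#'   added factors `speed_class` and `dir_sector`; attribute `edges`.
#' @export
classify_days <- function(wind, edges = c(-1, 1)) {
  stopifnot(is.data.frame(wind), all(c("date", "u10", "v10") %in% names(wind)))
  if (nrow(wind) == 0L) stop("empty wind series")
  edges <- sort(as.numeric(edges))
  if (length(edges) < 1L) stop("need at least one speed edge")
  k <- length(edges)
  labels <- c(sprintf("v < %g", edges[1]),
              if (k > 1) sprintf("%g <= v <= %g", edges[-k], edges[-1])
              else sprintf("%g <= v <= %g", edges[1], edges[1]),
              sprintf("v > %g", edges[k]))
  if (k == 1L) labels <- c(sprintf("v < %g", edges[1]), sprintf("v >= %g", edges[1]))
  v <- wind$v10
  if (k == 1L) {
    cls <- ifelse(v < edges[1], 1L, 2L)
  } else {
    # first class open below edges[1]; edges[1] and edges[k] closed into the
    # adjacent inner class; interior edges belong to the class below
    cls <- ifelse(v < edges[1], 1L, 2L + findInterval(v, edges[-1],
                                                      left.open = TRUE))
  }
  sector_names <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  theta <- (atan2(-wind$u10, -wind$v10) * 180 / pi) %% 360
  bounds <- 22.5 + 45 * (0:7)
  sec <- findInterval(theta, bounds, left.open = TRUE) + 1L
  sec[sec == 9L] <- 1L  # wrap (337.5, 360) back to N
  out <- wind
  out$speed_class <- factor(labels[cls], levels = labels)
  out$dir_sector <- factor(sector_names[sec], levels = sector_names)
  attr(out, "edges") <- edges
  class(out) <- c("day_classification", "data.frame")
  out
}

#' Empirical percentile level and exceedance mask of a frequency map
#'
#' The level is the empirical q-th percentile (linear interpolation between
#' order statistics) of the valid map values over the analysis domain; the
#' exceedance mask marks pixels at or above the level.
#'
#' @param map A [frequency_map()] (or composite class map).
#' @param q Percentile (default 90).
#' @param domain Optional logical matrix restricting the analysis domain
#'   (e.g. land pixels only).
#' @return List with `level` and `exceed` (logical matrix).
#' @export
class_percentile_level <- function(map, q = 90, domain = NULL) {
  vals <- map$values
  keep <- !is.na(vals)
  if (!is.null(domain)) keep <- keep & domain
  if (sum(keep) < 10L) stop("too few valid pixels for a percentile level")
  level <- stats::quantile(vals[keep], q / 100, names = FALSE, type = 7)
  exceed <- keep & vals >= level
  exceed[is.na(exceed)] <- FALSE
  list(level = level, exceed = exceed)
}

#' Wind-conditioned cloud-frequency composites
#'
#' Splits the season's days by wind class and computes one frequency map per
#' class together with its own q-th percentile level and exceedance mask
#' (per-class levels absorb differences in mean cloudiness between wind
#' regimes). Days without wind data are dropped with a warning; classes with
#' fewer than `min_days` days are dropped with a warning.
#'
#' @param masks A `cloud_mask` stack.
#' @param classification A [classify_days()] frame.
#' @param months Season months (default JJA).
#' @param q Percentile for the exceedance contour (default 90).
#' @param min_days Minimum days per retained class (default 1).
#' @param landcover Optional [build_landcover()] map; water pixels are then
#'   excluded from the percentile domain.
#' @param by Classification column to composite on (default `"speed_class"`).
#' @return An object of class `wind_composite`: `classes` (named list with
#'   `map`, `n_days`, `level`, `exceed`, `mean_v`, `mean_u`), `overall`
#'   (frequency map over all classified days), `q`, `by`.
#' @export
composite_frequency <- function(masks, classification, months = 6:8, q = 90,
                                min_days = 1, landcover = NULL,
                                by = "speed_class") {
  stopifnot(inherits(masks, "cloud_mask"),
            inherits(classification, "day_classification"))
  meta <- slot_meta(masks$time)
  slots <- select_slots(masks, months, NULL)
  if (length(slots) == 0L) stop("empty window: no slots selected")
  have_wind <- meta$date[slots] %in% classification$date
  if (!all(have_wind)) {
    warning(sprintf("%d days lack wind data and are dropped",
                    length(unique(meta$date[slots][!have_wind]))))
    slots <- slots[have_wind]
    if (length(slots) == 0L) stop("no classified days in window")
  }
  cls <- classification[[by]][match(meta$date[slots], classification$date)]
  domain <- if (!is.null(landcover)) landcover$classes != "water" else NULL

  classes <- list()
  retained <- integer(0)
  for (lv in levels(cls)) {
    s <- slots[cls == lv]
    days <- unique(meta$date[s])
    if (length(days) < min_days) {
      if (length(days) > 0L)
        warning(sprintf("class '%s' has %d day(s) < min_days and is dropped",
                        lv, length(days)))
      next
    }
    fm <- structure(c(freq_from_slots(masks$flags, s),
                      list(window = list(months = months, hours = NULL,
                                         n_total = length(s)))),
                    class = "frequency_map")
    pl <- class_percentile_level(fm, q = q, domain = domain)
    ci <- classification$date %in% days
    classes[[lv]] <- list(map = fm, n_days = length(days),
                          level = pl$level, exceed = pl$exceed,
                          mean_v = mean(classification$v10[ci]),
                          mean_u = mean(classification$u10[ci]))
    retained <- c(retained, s)
  }
  if (length(classes) == 0L) stop("no wind classes retained")
  overall <- structure(c(freq_from_slots(masks$flags, sort(retained)),
                         list(window = list(months = months, hours = NULL,
                                            n_total = length(retained)))),
                       class = "frequency_map")
  structure(list(classes = classes, overall = overall, q = q, by = by),
            class = "wind_composite")
}

#' @export
print.wind_composite <- function(x, ...) {
  cat(sprintf("<wind_composite (%s), q%g levels>\n", x$by, x$q))
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    cat(sprintf("  %-16s n_days=%3d  mean v=%+.2f m/s  level=%.3f\n",
                nm, cl$n_days, cl$mean_v, cl$level))
  }
  invisible(x)
}

#' Recombine wind-class composites into the overall frequency map
#'
#' Slot-weighted recombination from the per-class cloudy/valid counts; by
#' construction this reproduces the overall map exactly (partition
#' identity).
#'
#' @param composite A [composite_frequency()] result.
#' @return A `frequency_map`.
#' @export
recombine_composites <- function(composite) {
  stopifnot(inherits(composite, "wind_composite"))
  maps <- lapply(composite$classes, `[[`, "map")
  n_cloud <- Reduce(`+`, lapply(maps, `[[`, "n_cloud"))
  n_valid <- Reduce(`+`, lapply(maps, `[[`, "n_slots"))
  values <- n_cloud / n_valid
  values[n_valid == 0] <- NA_real_
  structure(list(values = values, n_slots = n_valid, n_cloud = n_cloud,
                 window = composite$overall$window),
            class = "frequency_map")
}

#' Centroid of an exceedance mask
#'
#' Mean (row, col) pixel position of the TRUE cells, used to measure the
#' downwind displacement of the high-frequency region.
#'
#' @param exceed Logical matrix.
#' @return Named numeric `c(row, col)`.
#' @export
mask_centroid <- function(exceed) {
  idx <- which(exceed, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty exceedance mask")
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)  # 0-based, row 0 north
}
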