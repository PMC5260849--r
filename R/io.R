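#' Write / read a box series as CSV
#'
#' Series frames (daily, dekadal, diurnal) round-trip through plain CSV with
#' ISO dates.
#'
#' @param series `data.frame` (any of the series produced by the package).
#' @param path File path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns the `data.frame` with `date` parsed when present.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}

#' Write / read a daily wind series (date, u10, v10) as CSV
#' @param wind `data.frame` with columns `date`, `u10`, `v10`.
#' @param path File path.
#' @export
write_wind_csv <- function(wind, path) {
  stopifnot(all(c("date", "u10", "v10") %in% names(wind)))
  utils::write.csv(wind[c("date", "u10", "v10")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wind_csv
#' @export
read_wind_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "u10", "v10") %in% names(d)))
    stop("wind CSV must have columns date, u10, v10")
  d$date <- as.Date(d$date)
  d
}

#' Write / read a frequency map as long-format CSV
#'
#' Rows are `(row, col)` 0-based pixel coordinates (row 0 = north) with the
#' frequency `value` and the valid/cloudy slot counts.
#'
#' @param map A [frequency_map()].
#' @param path File path.
#' @export
write_frequency_csv <- function(map, path) {
  stopifnot(inherits(map, "frequency_map"))
  ny <- nrow(map$values); nx <- ncol(map$values)
  d <- data.frame(row = rep(0:(ny - 1L), times = nx),
                  col = rep(0:(nx - 1L), each = ny),
                  value = as.vector(map$values),
                  n_slots = as.vector(map$n_slots),
                  n_cloud = as.vector(map$n_cloud))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_csv
#' @export
read_frequency_csv <- function(path) {
  d <- utils::read.csv(path)
  ny <- max(d$row) + 1L; nx <- max(d$col) + 1L
  idx <- cbind(d$row + 1L, d$col + 1L)
  values <- matrix(NA_real_, ny, nx); values[idx] <- d$value
  n_slots <- matrix(0L, ny, nx); n_slots[idx] <- d$n_slots
  n_cloud <- matrix(0L, ny, nx); n_cloud[idx] <- d$n_cloud
  structure(list(values = values, n_slots = n_slots, n_cloud = n_cloud,
                 window = list(months = NULL, hours = NULL,
                               n_total = NA_integer_)),
            class = "frequency_map")
}

#' Write / read a land-cover map as CSV + JSON sidecar
#'
#' The class raster goes to `<path>` as a headerless CSV of class codes
#' (`f` forest, `n` nonforest, `w` water); boxes, damage zone and pixel size
#' go to `<path>.json`.
#'
#' @param landcover A [build_landcover()] object.
#' @param path CSV file path.
#' @export
write_landcover <- function(landcover, path) {
  stopifnot(inherits(landcover, "landcover"))
  code <- matrix(substr(landcover$classes, 1, 1), landcover$ny, landcover$nx)
  utils::write.table(code, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(pixel_km = landcover$pixel_km,
               forest_rect = unclass(landcover$forest_rect),
               boxes = lapply(landcover$boxes, unclass),
               damage_zone = if (is.null(landcover$damage_zone)) NULL
                             else unclass(landcover$damage_zone))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_landcover
#' @export
read_landcover <- function(path) {
  code <- as.matrix(utils::read.table(path, sep = ",",
                                      colClasses = "character"))
  dimnames(code) <- NULL
  classes <- matrix(c(f = "forest", n = "nonforest", w = "water")[code],
                    nrow(code), ncol(code))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lc <- build_landcover(ncol(classes), nrow(classes),
                        forest_rect = as_rect(meta$forest_rect),
                        boxes = lapply(meta$boxes, as_rect),
                        damage_rect = if (is.null(meta$damage_zone)) NULL
                                      else as_rect(meta$damage_zone),
                        pixel_km = meta$pixel_km)
  lc$classes <- classes  # preserve any non-rectangular detail
  lc
}

#' Save / load stack objects (counts, masks, climatology, truth)
#'
#' Binary RDS convenience wrappers for in-session artifacts.
#'
#' @param x Object to save.
#' @param path File path.
#' @export
save_stack <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_stack
#' @export
load_stack <- function(path) readRDS(path)

#' Read a pipeline run configuration from YAML
#'
#' Fills defaults for any field not given; see [run_pipeline()] for the
#' recognised fields.
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  defaults <- list(
    grid = list(nx = 120L, ny = 120L,
                forest = c(30L, 90L, 30L, 90L),
                damage = NULL, water = NULL),
    start = "2008-01-01", end = "2010-12-31",
    months = NULL, daylight = c(6L, 18L), cadence_minutes = 60L,
    p_cloud_base = 0.3, delta_forest_jja = 0.10,
    cloud_boost_counts = 50, noise_sd = 2,
    wind_displacement_km_per_ms = 5, wind_sd = 2,
    klaus_date = "2009-01-24", klaus_residual_delta = 0.020,
    missing_rate = 0,
    threshold = 10, window_w = 3, min_samples = 20,
    n_boot = 1000, wind_edges = c(-1, 1),
    season_months = c(6L, 7L, 8L),
    seed = NULL)
  out <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  if (is.null(out$seed)) stop("run config requires a seed")
  structure(out, class = c("run_config", "list"))
}
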