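# slot selection by month / hour window
select_slots <- function(mask, months = NULL, hours = NULL, dates = NULL) {
  meta <- slot_meta(mask$time)
  keep <- rep(TRUE, length(mask$time))
  if (!is.null(months)) keep <- keep & meta$month %in% months
  if (!is.null(hours)) keep <- keep & meta$hour %in% hours
  if (!is.null(dates)) keep <- keep & meta$date %in% dates
  which(keep)
}

# cloud / valid / frequency matrices over a slot subset
freq_from_slots <- function(flags, slots) {
  f <- flags[, , slots, drop = FALSE]
  n_cloud <- rowSums(f == 1L, dims = 2, na.rm = TRUE)
  n_valid <- rowSums(!is.na(f), dims = 2)
  values <- n_cloud / n_valid
  values[n_valid == 0] <- NA_real_
  storage.mode(n_cloud) <- "integer"
  storage.mode(n_valid) <- "integer"
  list(values = values, n_slots = n_valid, n_cloud = n_cloud)
}

#' Per-pixel cloud-frequency map
#'
#' Fraction of valid daytime slots flagged cloudy per pixel, over a season
#' (month set) and hour window. Missing flags are excluded from both
#' numerator and denominator, so the frequency is conditional on a valid
#' observation.
#'
#' @param masks A `cloud_mask` stack.
#' @param months Integer months retained (`NULL` = all), e.g. `6:8` for JJA.
#' @param hours Integer UTC hours retained (`NULL` = all daylight hours).
#' @return An object of class `frequency_map`: `values` (ny x nx, in
#'   `[0, 1]`, `NA` where no valid slots), `n_slots`, `n_cloud`, `window`.
#' @export
frequency_map <- function(masks, months = NULL, hours = NULL) {
  stopifnot(inherits(masks, "cloud_mask"))
  slots <- select_slots(masks, months, hours)
  if (length(slots) == 0L) stop("empty window: no slots selected")
  res <- freq_from_slots(masks$flags, slots)
  structure(c(res, list(window = list(months = months, hours = hours,
                                      n_total = length(slots)))),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map %d x %d px, %d slots, mean %.3f>\n",
              nrow(x$values), ncol(x$values), x$window$n_total,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# mean over box pixels of per-pixel frequency within a slot subset
box_freq <- function(flags, box, slots) {
  f <- flags[rect_rows(box), rect_cols(box), slots, drop = FALSE]
  n_cloud <- rowSums(f == 1L, dims = 2, na.rm = TRUE)
  n_valid <- rowSums(!is.na(f), dims = 2)
  px <- n_cloud / n_valid
  list(value = mean(px[n_valid > 0]), n = sum(n_valid))
}

#' Daily box-mean cloud-frequency series
#'
#' One value per calendar day: the mean over the box pixels of that day's
#' per-pixel cloud frequency. Days without any valid slot are missing.
#'
#' @param masks A `cloud_mask` stack.
#' @param box Analysis rectangle ([rect()]).
#' @param hours,months Optional hour / month restriction.
#' @return `data.frame` with columns `date`, `year`, `dekad`, `value`, `n`
#'   (valid slot-pixels contributing).
#' @export
box_daily_series <- function(masks, box, hours = NULL, months = NULL) {
  stopifnot(inherits(masks, "cloud_mask"))
  box <- as_rect(box)
  dims <- dim(masks$flags)
  if (!rect_in_grid(box, dims[1], dims[2])) stop("box out of grid bounds")
  slots <- select_slots(masks, months, hours)
  if (length(slots) == 0L) stop("empty window: no slots selected")
  meta <- slot_meta(masks$time)
  by_day <- split(slots, meta$date[slots])
  days <- as.Date(names(by_day))
  vals <- vapply(by_day, function(s) {
    bf <- box_freq(masks$flags, box, s)
    c(bf$value, bf$n)
  }, numeric(2))
  out <- data.frame(date = days,
                    year = as.integer(format(days, "%Y")),
                    dekad = dekad_of_date(days),
                    value = vals[1, ], n = as.integer(vals[2, ]))
  out$value[out$n == 0L] <- NA_real_
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Dekadal forest-minus-nonforest difference series
#'
#' For every (year, dekad) present in the record: the box-mean cloud
#' frequency over the forest box minus the equal-weight mean of the
#' non-forest boxes' frequencies. This is the series the squared-sine
#' breakpoint model is fitted to.
#'
#' @param masks A `cloud_mask` stack.
#' @param forest_box Forest rectangle.
#' @param nonforest_boxes List of non-forest rectangles (pooled with equal
#'   weight per box).
#' @param hours Optional hour restriction.
#' @return `data.frame` with columns `date` (mid-dekad), `year`, `dekad`,
#'   `value` (difference), `forest`, `nonforest`, `n` (valid forest
#'   slot-pixels).
#' @export
dekadal_difference_series <- function(masks, forest_box, nonforest_boxes,
                                      hours = NULL) {
  stopifnot(inherits(masks, "cloud_mask"))
  forest_box <- as_rect(forest_box)
  if (inherits(nonforest_boxes, "fc_rect")) nonforest_boxes <- list(nonforest_boxes)
  nonforest_boxes <- lapply(nonforest_boxes, as_rect)
  slots <- select_slots(masks, NULL, hours)
  if (length(slots) == 0L) stop("empty window: no slots selected")
  meta <- slot_meta(masks$time)
  key <- meta$year[slots] * 100L + meta$dekad[slots]
  by_dk <- split(slots, key)
  keys <- as.integer(names(by_dk))
  rows <- lapply(seq_along(by_dk), function(i) {
    s <- by_dk[[i]]
    fo <- box_freq(masks$flags, forest_box, s)
    nf <- vapply(nonforest_boxes, function(b) box_freq(masks$flags, b, s)$value,
                 numeric(1))
    year <- keys[i] %/% 100L; dk <- keys[i] %% 100L
    data.frame(date = dekad_start(year, dk) + 4L, year = year, dekad = dk,
               value = fo$value - mean(nf), forest = fo$value,
               nonforest = mean(nf), n = fo$n)
  })
  out <- do.call(rbind, rows)
  out[order(out$date), , drop = FALSE]
}

#' Diurnal cycle of box-mean cloud frequency
#'
#' Mean cloud frequency over the box for every integer UTC hour of the
#' daylight window, pooling all days of the season.
#'
#' @param masks A `cloud_mask` stack.
#' @param box Analysis rectangle.
#' @param months Season months (default JJA, `6:8`).
#' @return `data.frame` with columns `hour`, `value`, `n`.
#' @export
diurnal_cycle <- function(masks, box, months = 6:8) {
  stopifnot(inherits(masks, "cloud_mask"))
  box <- as_rect(box)
  slots <- select_slots(masks, months, NULL)
  if (length(slots) == 0L) stop("empty window: no slots selected")
  meta <- slot_meta(masks$time)
  by_hour <- split(slots, meta$hour[slots])
  vals <- vapply(by_hour, function(s) {
    bf <- box_freq(masks$flags, box, s)
    c(bf$value, bf$n)
  }, numeric(2))
  data.frame(hour = as.integer(names(by_hour)),
             value = vals[1, ], n = as.integer(vals[2, ]),
             row.names = NULL)
}

#' Daily box series tagged with a climatology bin (for bootstrap intervals)
#'
#' Convenience wrapper returning the daily series of a box with the `bin`
#' column the bootstrap utilities expect (here the dekad of year, pooling
#' years).
#'
#' @inheritParams box_daily_series
#' @return `data.frame` with columns `date`, `bin`, `value`, `n`.
#' @export
box_daily_by_dekad <- function(masks, box, hours = NULL, months = NULL) {
  d <- box_daily_series(masks, box, hours = hours, months = months)
  data.frame(date = d$date, bin = d$dekad, value = d$value, n = d$n)
}
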