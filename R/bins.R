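#' Climatology bin scheme: 36 dekads x daylight hours
#'
#' The clear-sky climatology is estimated independently for every
#' (10-day period, hour-of-day) combination. The year is split into 36
#' dekads (the last absorbing days 351 to year end) and hours are the integer
#' UTC hours of the half-open daylight window.
#'
#' @param daylight Length-2 half-open UTC hour window (default `c(6, 18)`).
#' @return An object of class `bin_scheme` with fields `hours`, `n_dekads`,
#'   `n_hours`, `n_bins`.
#' @export
bin_scheme <- function(daylight = c(6, 18)) {
  daylight <- as.integer(daylight)
  if (length(daylight) != 2L || daylight[2] <= daylight[1])
    stop("daylight window must be an increasing pair of hours")
  hours <- seq.int(daylight[1], daylight[2] - 1L)
  structure(list(daylight = daylight, hours = hours,
                 n_dekads = 36L, n_hours = length(hours),
                 n_bins = 36L * length(hours)),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme 36 dekads x %d hours [%02d..%02d] = %d bins>\n",
              x$n_hours, x$hours[1], x$hours[x$n_hours], x$n_bins))
  invisible(x)
}

#' Map timestamps to (dekad, hour) climatology bins
#'
#' @param time `POSIXct` (UTC) timestamps; every timestamp must fall inside
#'   the scheme's daylight window.
#' @param scheme A [bin_scheme()].
#' @return `data.frame` with columns `dekad` (1..36), `hour` (UTC integer
#'   hour) and `bin` (1-based linear bin index, hour varying fastest).
#' @examples
#' sc <- bin_scheme()
#' time_bin(as.POSIXct("2006-01-01 06:10", tz = "UTC"), sc)  # dekad 1, hour 6
#' @export
time_bin <- function(time, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  meta <- slot_meta(time)
  if (any(meta$hour < scheme$daylight[1] | meta$hour >= scheme$daylight[2]))
    stop("timestamp outside the daylight window")
  hpos <- match(meta$hour, scheme$hours)
  data.frame(dekad = meta$dekad, hour = meta$hour,
             bin = (meta$dekad - 1L) * scheme$n_hours + hpos)
}

# (dekad, hour) labels for each linear bin index
bin_labels <- function(scheme) {
  data.frame(bin = seq_len(scheme$n_bins),
             dekad = rep(seq_len(36L), each = scheme$n_hours),
             hour = rep(scheme$hours, times = 36L))
}
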