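#' Slot calendar for a 15-min daytime imaging record
#'
#' Describes the retained image slots of a geostationary record: consecutive
#' calendar days between `start` and `end` (optionally restricted to a set of
#' months), each contributing slots at `cadence_minutes` within the half-open
#' daylight window `[daylight[1], daylight[2])` UTC. The default window
#' 06:00-18:00 at 15 min gives 48 slots per day.
#'
#' @param start,end First and last calendar day (`Date` or yyyy-mm-dd string),
#'   inclusive.
#' @param cadence_minutes Imaging cadence; must divide 60.
#' @param daylight Length-2 integer vector, half-open UTC hour window.
#' @param months Optional integer months (e.g. `6:8` for JJA) retained.
#' @return An object of class `slot_calendar`.
#' @examples
#' cal <- slot_calendar("2004-01-01", "2013-12-31", months = 6:8)
#' count_slots(cal)  # 44160
#' @export
slot_calendar <- function(start, end, cadence_minutes = 15,
                          daylight = c(6, 18), months = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid calendar dates")
  if (end < start) stop("calendar end precedes start")
  cadence_minutes <- as.integer(cadence_minutes)
  if (cadence_minutes <= 0L || 60L %% cadence_minutes != 0L)
    stop("cadence must be a positive divisor of 60 minutes")
  daylight <- as.integer(daylight)
  if (length(daylight) != 2L || daylight[1] < 0L || daylight[2] > 24L ||
      daylight[2] <= daylight[1])
    stop("daylight window must be an increasing pair of hours in [0, 24]")
  if (!is.null(months)) {
    months <- sort(unique(as.integer(months)))
    if (any(months < 1L | months > 12L)) stop("months must be in 1..12")
  }
  structure(list(start = start, end = end,
                 cadence_minutes = cadence_minutes,
                 daylight = daylight, months = months),
            class = "slot_calendar")
}

calendar_days <- function(cal) {
  days <- seq(cal$start, cal$end, by = "day")
  if (!is.null(cal$months)) {
    m <- as.integer(format(days, "%m"))
    days <- days[m %in% cal$months]
  }
  days
}

slots_per_day <- function(cal) {
  ((cal$daylight[2] - cal$daylight[1]) * 60L) %/% cal$cadence_minutes
}

#' Exact count of retained image slots
#'
#' Days in the calendar (after the month filter) times slots per day; the
#' half-open daylight window makes the per-day count exact.
#'
#' @param cal A [slot_calendar()].
#' @return Integer slot count.
#' @export
count_slots <- function(cal) {
  stopifnot(inherits(cal, "slot_calendar"))
  length(calendar_days(cal)) * slots_per_day(cal)
}

#' All slot timestamps of a calendar
#'
#' @param cal A [slot_calendar()].
#' @return `POSIXct` (UTC) vector, strictly increasing, of length
#'   [count_slots()].
#' @export
slot_times <- function(cal) {
  days <- calendar_days(cal)
  offs <- seq(cal$daylight[1] * 3600L,
              cal$daylight[2] * 3600L - cal$cadence_minutes * 60L,
              by = cal$cadence_minutes * 60L)
  base <- as.POSIXct(as.character(days), tz = "UTC")
  res <- rep(base, each = length(offs)) + rep(offs, times = length(days))
  attr(res, "tzone") <- "UTC"
  res
}

#' @export
print.slot_calendar <- function(x, ...) {
  cat(sprintf("<slot_calendar %s .. %s, %d-min, [%02d:00,%02d:00) UTC%s: %d slots>\n",
              format(x$start), format(x$end), x$cadence_minutes,
              x$daylight[1], x$daylight[2],
              if (is.null(x$months)) "" else
                paste0(", months ", paste(x$months, collapse = ",")),
              count_slots(x)))
  invisible(x)
}

#' Dekad (10-day period) of a calendar date
#'
#' Dekad `d` covers days-of-year `(d-1)*10 + 1 .. d*10`; dekad 36 absorbs the
#' remainder of the year (days 351 to 365/366).
#'
#' @param date `Date` vector.
#' @return Integer vector in 1..36.
#' @export
dekad_of_date <- function(date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  pmin((doy - 1L) %/% 10L + 1L, 36L)
}

# first calendar day of a dekad within a year
dekad_start <- function(year, dekad) {
  as.Date(sprintf("%04d-01-01", year)) + (dekad - 1L) * 10L
}

# per-slot metadata used by the aggregation stages
slot_meta <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  lt <- as.POSIXlt(time, tz = "UTC")
  date <- as.Date(time, tz = "UTC")
  data.frame(date = date,
             year = lt$year + 1900L,
             month = lt$mon + 1L,
             doy = lt$yday + 1L,
             hour = lt$hour,
             dekad = pmin(lt$yday %/% 10L + 1L, 36L))
}
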