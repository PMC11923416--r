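#' Dates covered by an integration window
#'
#' Inclusive window ending on the sampling date: a 1-day window is the
#' sampling day itself, a 2-day window adds the preceding day, and so on.
#' Week windows follow the same convention (`7 * length` days ending on the
#' sampling date) with the special case `length = 0` meaning the sampling
#' day alone. Dates before `floor_date` are removed and the result carries
#' a `"truncated"` attribute when clipping occurred.
#'
#' @param sampling_date Date of the sampling event.
#' @param length Window length (days >= 1, or weeks >= 0).
#' @param unit `"days"` or `"weeks"`.
#' @param floor_date Earliest usable date; `NULL` to disable.
#' @return Vector of dates, earliest first.
#' @examples
#' window_dates(as.Date("2019-06-12"), 2, "days")
#' @export
window_dates <- function(sampling_date, length, unit = "days",
                         floor_date = NULL) {
  sampling_date <- as.Date(sampling_date)
  unit <- match.arg(unit, c("days", "weeks"))
  if (length < 0) stop("window length must be >= 0")
  if (unit == "days" && length < 1) stop("day windows must be >= 1 day")
  ndays <- if (unit == "days") length else max(1, 7 * length)
  dates <- seq(sampling_date - (ndays - 1), sampling_date, by = 1)
  truncated <- FALSE
  if (!is.null(floor_date)) {
    floor_date <- as.Date(floor_date)
    truncated <- any(dates < floor_date)
    dates <- dates[dates >= floor_date]
  }
  attr(dates, "truncated") <- truncated
  dates
}

# Per-day daytime sum and count for one driver column (one pass over the
# timestamps; window means are then exact pooled means of these stats).
daytime_daily_stats <- function(series, driver = "value", daytime = c(9, 15)) {
  if ("timestamp" %in% names(series)) {
    d <- as.Date(series$timestamp, tz = ISO_TZ)
    hour <- as.integer(format(series$timestamp, "%H")) +
      as.numeric(format(series$timestamp, "%M")) / 60
    sel <- hour >= daytime[1] & hour < daytime[2] & !is.na(series[[driver]])
    if (!any(sel)) {
      return(data.frame(date = as.Date(character(0)), sum = numeric(0),
                        n = integer(0)))
    }
    agg <- rowsum(cbind(sum = series[[driver]][sel], n = 1), group = d[sel])
    data.frame(date = as.Date(rownames(agg)), sum = agg[, "sum"],
               n = as.integer(agg[, "n"]), row.names = NULL)
  } else {
    ok <- !is.na(series$value)
    data.frame(date = series$date[ok], sum = series$value[ok],
               n = rep(1L, sum(ok)))
  }
}

# pooled mean over window dates from precomputed daily stats
window_value <- function(daily, dates) {
  sel <- daily$date %in% dates
  n <- sum(daily$n[sel])
  list(value = if (n > 0) sum(daily$sum[sel]) / n else NA_real_,
       n_halfhours = n)
}

#' Daytime-filtered window mean of a driver
#'
#' Mean of all half-hour values whose clock time falls in the half-open
#' daytime interval (default 09:00-15:00) on the window dates. Missing
#' values are excluded from both numerator and denominator. Daily series
#' (data frames with `date` and `value` columns) skip the daytime filter:
#' they have no sub-daily structure.
#'
#' @param series Half-hourly data frame with `timestamp` and the driver
#'   column, or a daily data frame with `date` and `value`.
#' @param driver Driver column name (ignored for daily series).
#' @param dates Window dates (from [window_dates()]).
#' @param daytime Clock-hour bounds, half-open `[start, end)`.
#' @return List `value` (NA when no data contribute) and `n_halfhours`.
#' @export
integrate_driver <- function(series, driver = "value", dates,
                             daytime = c(9, 15)) {
  window_value(daytime_daily_stats(series, driver, daytime), as.Date(dates))
}

#' Build the time-integrated predictor table
#'
#' For every sampling event, driver and window length, computes the
#' daytime-filtered window mean ending on the sampling date. Windows are
#' clipped at `floor_date` (modeled isotope drivers are undefined before
#' it) and the clipping is flagged, not dropped — early-season events keep
#' their shortened windows. Windows contributing fewer than
#' `min_coverage` of the expected half-hours are flagged `low_coverage`.
#'
#' @param events Sampling-event data frame (`tree_id`, `date`,
#'   `needle_age`).
#' @param drivers Named list of driver series: half-hourly data frames with
#'   `timestamp` + the driver column of the same name, or daily data frames
#'   with `date` + `value`.
#' @param windows Integer window lengths.
#' @param unit `"days"` or `"weeks"`.
#' @param floor_date Earliest usable date (default `"2019-04-01"`).
#' @param daytime Daytime clock bounds, see [integrate_driver()].
#' @param min_coverage Minimum fraction of expected half-hours (default
#'   0.25) below which the row is flagged.
#' @return Long data frame of class `integration_table`: `tree_id`, `date`,
#'   `needle_age`, `driver`, `window`, `unit`, `value`, `n_halfhours`,
#'   `truncated`, `low_coverage`, ordered deterministically.
#' @export
build_integration_table <- function(events, drivers, windows, unit = "days",
                                    floor_date = "2019-04-01",
                                    daytime = c(9, 15), min_coverage = 0.25) {
  stopifnot(length(windows) >= 1, is.list(drivers),
            !is.null(names(drivers)))
  grid <- expand.grid(event = seq_len(nrow(events)),
                      driver = names(drivers), window = windows,
                      stringsAsFactors = FALSE)
  halfhours_per_day <- (daytime[2] - daytime[1]) * 2
  stats <- lapply(names(drivers), function(drv) {
    daytime_daily_stats(drivers[[drv]], drv, daytime)
  })
  names(stats) <- names(drivers)
  is_daily <- !vapply(drivers, function(d) "timestamp" %in% names(d),
                      logical(1))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- events[grid$event[i], ]
    drv <- grid$driver[i]
    w <- grid$window[i]
    dts <- window_dates(ev$date, w, unit, floor_date = floor_date)
    res <- window_value(stats[[drv]], dts)
    expected <- if (is_daily[[drv]]) {
      length(dts)
    } else {
      length(dts) * halfhours_per_day
    }
    data.frame(tree_id = ev$tree_id, date = ev$date,
               needle_age = ev$needle_age, driver = drv,
               window = w, unit = unit, value = res$value,
               n_halfhours = res$n_halfhours,
               truncated = attr(dts, "truncated"),
               low_coverage = res$n_halfhours < min_coverage * expected)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$driver, out$window, out$needle_age, out$date,
                   out$tree_id), ]
  rownames(out) <- NULL
  class(out) <- c("integration_table", "data.frame")
  out
}
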