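#' Longitude-derived standard UTC offset
#'
#' Whole-hour offset of local standard time from UTC, `round(lon / 15)` with
#' ties away from zero. Using the solar offset rather than civil time zones
#' keeps the daily window deterministic and free of any time-zone database;
#' the afternoon temperature peak this pipeline cares about is tied to solar
#' time anyway.
#'
#' @param lon longitude(s) in degrees, -180..180
#' @return integer offset(s) in hours (negative west of Greenwich)
#' @examples
#' local_utc_offset(c(0, -90, -122.4))  # 0, -6, -8
#' @export
local_utc_offset <- function(lon) {
  stopifnot(all(is.finite(lon)), all(lon >= -180), all(lon <= 180))
  as.integer(sign(lon) * floor(abs(lon) / 15 + 0.5))
}

#' Hourly 2 m air-temperature cube on a coarse grid
#'
#' @param spec a [grid_spec()] (the coarse reanalysis grid)
#' @param times `POSIXct` UTC instants, strictly increasing with a uniform
#'   one-hour step
#' @param values numeric array `[time, row, col]` of temperatures (°C);
#'   `NA` marks missing samples
#' @return an object of class `hourly_cube`
#' @export
hourly_cube <- function(spec, times, values) {
  stopifnot(inherits(spec, "grid_spec"), inherits(times, "POSIXct"))
  dt <- diff(as.numeric(times))
  if (length(dt) && (any(dt <= 0) || any(abs(dt - 3600) > 1e-6)))
    stop("timestamps must strictly increase with a uniform hourly step",
         call. = FALSE)
  values <- as.array(values)
  if (!all(dim(values) == c(length(times), spec$nrows, spec$ncols)))
    stop("values must be a [time, row, col] array matching times and spec",
         call. = FALSE)
  structure(list(spec = spec, times = times, values = values),
            class = "hourly_cube")
}

#' @export
print.hourly_cube <- function(x, ...) {
  cat(sprintf("<hourly_cube> %s, %d hourly steps %s .. %s UTC\n",
              format(x$spec), length(x$times),
              format(min(x$times), "%Y-%m-%d %H:%M"),
              format(max(x$times), "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Daily temperature extrema in local standard time
#'
#' Reduces an hourly cube to the per-pixel maximum (and minimum) over the 24
#' hourly samples of one local calendar day, midnight to midnight local
#' standard time. Each pixel column uses its own longitude-derived UTC
#' offset, so a domain spanning several 15-degree bands is handled
#' correctly. A pixel with any missing hourly sample inside its window is
#' flagged invalid rather than given a partial (cold-biased) maximum.
#'
#' Because the underlying reanalysis is interpolated from 3-hourly analysis
#' fields, maxima derived this way sit slightly below what a continuously
#' observing station would record; that bias direction is inherent to the
#' input, not to this reduction.
#'
#' @param cube an [hourly_cube()]
#' @param date the local calendar day (`Date` or ISO-8601 string)
#' @return an object of class `daily_extrema`: list with `spec`, `date`,
#'   `tmax` and `tmin` ([field2d()] objects)
#' @export
daily_extrema <- function(cube, date) {
  stopifnot(inherits(cube, "hourly_cube"))
  date <- as.Date(date)
  spec <- cube$spec
  offsets <- local_utc_offset(x_centers(spec))  # per column
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tnum <- as.numeric(cube$times)
  tmax <- matrix(NA_real_, spec$nrows, spec$ncols)
  tmin <- matrix(NA_real_, spec$nrows, spec$ncols)
  for (off in unique(offsets)) {
    cols <- which(offsets == off)
    want <- as.numeric(midnight) - off * 3600 + (0:23) * 3600
    idx <- match(want, tnum)
    if (anyNA(idx)) {
      miss <- want[is.na(idx)]
      stop(sprintf(
        "hourly cube does not cover local day %s (UTC offset %+d): missing %s .. %s UTC",
        format(date), off,
        format(as.POSIXct(min(miss), tz = "UTC"), "%Y-%m-%d %H:%M"),
        format(as.POSIXct(max(miss), tz = "UTC"), "%Y-%m-%d %H:%M")),
        call. = FALSE)
    }
    sl <- cube$values[idx, , cols, drop = FALSE]
    tmax[, cols] <- apply(sl, c(2, 3), function(v) if (anyNA(v)) NA_real_ else max(v))
    tmin[, cols] <- apply(sl, c(2, 3), function(v) if (anyNA(v)) NA_real_ else min(v))
  }
  structure(list(spec = spec, date = date,
                 tmax = field2d(spec, tmax),
                 tmin = field2d(spec, tmin)),
            class = "daily_extrema")
}

#' @export
print.daily_extrema <- function(x, ...) {
  cat(sprintf("<daily_extrema> %s on %s\n", format(x$date), format(x$spec)))
  cat("  tmax: "); print(x$tmax)
  invisible(x)
}
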