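#' A recurring month-day window over a set of years
#'
#' @param start,end `"MM-DD"` strings; `end` must not precede `start`
#'   within a year
#' @param years integer years
#' @return an object of class `date_window`
#' @examples
#' w <- date_window("06-01", "08-31", 2009:2011)
#' length(window_dates(w))  # 276 candidate days
#' @export
date_window <- function(start = "06-01", end = "08-31", years) {
  stopifnot(grepl("^\\d{2}-\\d{2}$", start), grepl("^\\d{2}-\\d{2}$", end),
            length(years) >= 1L)
  years <- as.integer(sort(unique(years)))
  probe <- as.Date(paste0(years[1], "-", c(start, end)))
  if (anyNA(probe) || probe[2] < probe[1])
    stop("invalid month-day window ", start, " .. ", end, call. = FALSE)
  structure(list(start = start, end = end, years = years),
            class = "date_window")
}

#' @rdname date_window
#' @export
window_dates <- function(window) {
  stopifnot(inherits(window, "date_window"))
  do.call(c, lapply(window$years, function(y) {
    seq(as.Date(paste0(y, "-", window$start)),
        as.Date(paste0(y, "-", window$end)), by = "day")
  }))
}

#' @export
print.date_window <- function(x, ...) {
  cat(sprintf("<date_window> %s .. %s of %s (%d candidate days)\n",
              x$start, x$end, paste(x$years, collapse = ", "),
              length(window_dates(x))))
  invisible(x)
}

#' Pair gridded estimates with station observations
#'
#' Inner-joins per-date gridded estimates with station observations on
#' `(station_id, date)`, restricted to a seasonal window. Dates where either
#' side is missing are dropped and counted, never imputed.
#'
#' @param estimates data frame with `station_id`, `date`, `estimate` (°C)
#' @param observations station table with `station_id`, `date`,
#'   `obs_tmax_c` (°C), e.g. from [read_stations()]
#' @param window a [date_window()]
#' @return a data frame of class `pair_series` with columns `station_id`,
#'   `date`, `estimate`, `observation`, sorted by station then date, with
#'   attributes `n_candidate` (window days per station) and `n_dropped`
#'   (candidate station-days lost to missingness)
#' @export
pair_series <- function(estimates, observations, window) {
  stopifnot(is.data.frame(estimates), is.data.frame(observations),
            inherits(window, "date_window"),
            all(c("station_id", "date", "estimate") %in% names(estimates)),
            all(c("station_id", "date", "obs_tmax_c") %in% names(observations)))
  dates <- window_dates(window)
  est <- estimates[estimates$date %in% dates & is.finite(estimates$estimate), ]
  obs <- observations[observations$date %in% dates &
                        is.finite(observations$obs_tmax_c), ]
  m <- merge(est[, c("station_id", "date", "estimate")],
             obs[, c("station_id", "date", "obs_tmax_c")],
             by = c("station_id", "date"))
  if (nrow(m) == 0L)
    stop(sprintf(
      "no overlapping estimate/observation dates in window %s .. %s of %s",
      window$start, window$end, paste(window$years, collapse = ",")),
      call. = FALSE)
  names(m)[names(m) == "obs_tmax_c"] <- "observation"
  m <- m[order(m$station_id, m$date), ]
  rownames(m) <- NULL
  stations <- unique(c(est$station_id, obs$station_id))
  structure(m,
            class = c("pair_series", "data.frame"),
            n_candidate = length(dates),
            n_dropped = length(dates) * length(stations) - nrow(m))
}

#' Validation statistics per station
#'
#' The two headline metrics for a gridded temperature product against
#' stations, with the sign convention estimate minus observation (negative
#' mean difference = the product runs cold):
#' `mean_diff = mean(est - obs)` and `rmsd = sqrt(mean((est - obs)^2))`.
#' `rmsd >= |mean_diff|` always.
#'
#' @param pairs a [pair_series()] (may hold several stations)
#' @return data frame with one row per station: `station_id`, `n`,
#'   `mean_diff`, `rmsd`
#' @export
compute_stats <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("station_id", "estimate", "observation") %in% names(pairs)))
  if (nrow(pairs) == 0L)
    stop("cannot compute validation statistics on an empty series",
         call. = FALSE)
  out <- do.call(rbind, lapply(split(pairs, pairs$station_id), function(p) {
    dd <- p$estimate - p$observation
    data.frame(station_id = p$station_id[1], n = length(dd),
               mean_diff = mean(dd), rmsd = sqrt(mean(dd^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate per-city validation rows
#'
#' Unweighted mean of every numeric metric column across cities, grouped by
#' `product` when that column is present — the multi-city summary row of a
#' validation table. Permutation-invariant by construction.
#'
#' @param stats data frame with a `city` column, optionally a `product`
#'   column, and numeric metric columns (e.g. `mean_diff`, `rmsd`)
#' @param label label for the summary row(s) (default `"mean"`)
#' @return data frame with one row per product (or a single row)
#' @export
aggregate_cities <- function(stats, label = "mean") {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1L)
  num <- names(stats)[vapply(stats, is.numeric, logical(1))]
  num <- setdiff(num, "n")
  agg_one <- function(df, prod) {
    row <- data.frame(city = label, stringsAsFactors = FALSE)
    if (!is.null(prod)) row$product <- prod
    for (m in num) row[[m]] <- mean(df[[m]])
    if ("n" %in% names(df)) row$n <- sum(df$n)
    row
  }
  if ("product" %in% names(stats)) {
    out <- do.call(rbind, lapply(split(stats, stats$product),
                                 function(df) agg_one(df, df$product[1])))
    rownames(out) <- NULL
    out
  } else {
    agg_one(stats, NULL)
  }
}

#' Round for reporting
#'
#' Half-away-from-zero rounding (the convention of printed validation
#' tables), as opposed to base R's round-half-even.
#'
#' @param x numeric
#' @param digits decimal places (default 2)
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
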