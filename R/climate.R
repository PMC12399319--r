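## Monthly climate anomalies and absolute window aggregation.
##
## Raw station data arrive as one row per (year, month) with one column per
## climate variable (total precipitation, min/mean/max temperature, and
## optionally an externally computed drought index).  All downstream
## analyses work on per-calendar-month z-scores ("anomalies"): each January
## is standardized against the mean and SD of all Januaries in a reference
## period, and so on.  Candidate climate predictors are means of these
## anomalies over "absolute" windows of whole months counted backwards from
## a fixed census date (30 June by convention).

#' Convert a monthly climate series to per-calendar-month anomalies
#'
#' Each observation is standardized against the mean and standard deviation
#' of its calendar month within the reference period, so that (for example)
#' a value of +1 means "one reference-period SD wetter/warmer than a typical
#' month of that name".  Rows outside the reference period are standardized
#' against the same reference statistics.
#'
#' @param climate Data frame with columns `year`, `month` (1-12) and the
#'   variable column named by `variable`.
#' @param variable Name of the climate variable column to standardize.
#' @param reference_period Integer vector of length 2, `c(first, last)`
#'   year of the reference period (inclusive). Defaults to the full span of
#'   the series.
#' @return An object of class `anomaly_series`: a data frame with columns
#'   `year`, `month`, `anomaly`, carrying the variable name and the
#'   per-calendar-month reference statistics as attributes (`variable`,
#'   `reference`).
#' @details The reference SD uses the sample (n-1) denominator. A reference
#'   month observed fewer than twice, or with zero SD, is an error: such a
#'   series cannot be standardized.
#' @examples
#' clim <- generate_climate(10, seed = 1)
#' an <- monthly_anomalies(clim, "prcp")
#' head(an)
#' @export
monthly_anomalies <- function(climate, variable,
                              reference_period = range(climate$year)) {
  assert_columns(climate, c("year", "month", variable), "climate table")
  if (length(reference_period) != 2L || reference_period[1] > reference_period[2]) {
    stop_dunesync("reference_period must be c(first_year, last_year)")
  }
  ref <- climate[climate$year >= reference_period[1] &
                   climate$year <= reference_period[2], ]
  stats_by_month <- lapply(1:12, function(m) {
    x <- ref[[variable]][ref$month == m]
    if (length(x) < 2L) {
      stop_dunesync(sprintf(
        "reference period has %d observation(s) of calendar month %d; need >= 2",
        length(x), m))
    }
    c(mean = mean(x), sd = stats::sd(x))
  })
  refstats <- data.frame(month = 1:12, do.call(rbind, stats_by_month))
  dev <- climate[[variable]] - refstats$mean[climate$month]
  zero_sd <- refstats$sd[climate$month] == 0
  if (any(zero_sd & dev != 0)) {
    bad <- unique(climate$month[zero_sd & dev != 0])
    stop_dunesync("zero reference SD for calendar month(s) with varying ",
                  "values: ", paste(sort(bad), collapse = ", "))
  }
  out <- data.frame(
    year = climate$year,
    month = climate$month,
    ## a degenerate month (zero SD, all values at the reference mean) has
    ## anomaly 0 by definition
    anomaly = ifelse(zero_sd, 0, dev / refstats$sd[climate$month])
  )
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  structure(out,
            variable = variable,
            reference = refstats,
            reference_period = as.integer(reference_period),
            class = c("anomaly_series", "data.frame"))
}

#' Specify an absolute climate window
#'
#' A window is a contiguous run of whole months counted backwards from the
#' census month (30 June of the second year of a transition, by default).
#' Offset 0 is the census month itself; offset k is k months earlier.  The
#' window contains every month with `close <= offset <= open`.
#'
#' @param open,close Month offsets, `0 <= close <= open`.
#' @return A list of class `window_spec` with elements `open` and `close`.
#' @examples
#' window_spec(4, 0)  # census month and the four months before it
#' @export
window_spec <- function(open, close) {
  open <- as.integer(open); close <- as.integer(close)
  if (is.na(open) || is.na(close) || close < 0L || open < close) {
    stop_dunesync("window requires 0 <= close <= open")
  }
  structure(list(open = open, close = close), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window: open %d, close %d (%d month%s)>\n",
              x$open, x$close, x$open - x$close + 1L,
              if (x$open == x$close) "" else "s"))
  invisible(x)
}

## Resolve a month offset (0 = anchor month of census_year) to (year, month).
offset_to_month <- function(census_year, offset, anchor_month = 6L) {
  k <- anchor_month - offset          # can be <= 0
  year <- census_year + (k - 1L) %/% 12L
  month <- (k - 1L) %% 12L + 1L
  data.frame(year = year, month = month)
}

## Inverse of offset_to_month.
month_to_offset <- function(census_year, year, month, anchor_month = 6L) {
  as.integer((census_year - year) * 12L + anchor_month - month)
}

#' Mean anomaly over an absolute window
#'
#' Averages the monthly anomalies over the window's months, with offsets
#' resolved backwards from the anchor month (June) of `census_year`.
#'
#' @param anoms An [monthly_anomalies()] series.
#' @param census_year Calendar year whose census date anchors the window.
#' @param window A [window_spec()] (or list with `open`, `close`).
#' @param anchor_month Census month (default 6, i.e. 30 June).
#' @return The arithmetic mean of the window's monthly z-scores.
#' @details Months missing from the series are an error, never silently
#'   skipped: a silently shortened window would bias its mean.
#' @examples
#' clim <- generate_climate(10, seed = 1, start_year = 2001)
#' an <- monthly_anomalies(clim, "prcp")
#' window_mean(an, 2008, window_spec(4, 0))  # Feb-Jun 2008
#' @export
window_mean <- function(anoms, census_year, window, anchor_month = 6L) {
  stopifnot(inherits(anoms, "anomaly_series"))
  months <- offset_to_month(census_year, seq(window$close, window$open),
                            anchor_month = anchor_month)
  key <- anoms$year * 12L + anoms$month
  idx <- match(months$year * 12L + months$month, key)
  if (anyNA(idx)) {
    miss <- months[is.na(idx), ]
    stop_dunesync("window months missing from anomaly series: ",
                  paste(sprintf("%d-%02d", miss$year, miss$month),
                        collapse = ", "))
  }
  mean(anoms$anomaly[idx])
}
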