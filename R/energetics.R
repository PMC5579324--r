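#' Energy expenditure from gas exchange
#'
#' Weir-type equation used by portable indirect calorimeters with zero
#' urinary nitrogen: `EE (kcal/min) = 3.781 * VO2 + 1.237 * VCO2`, with both
#' gas rates in L/min.
#'
#' @param vo2 oxygen uptake, L/min (>= 0, vectorised).
#' @param vco2 carbon dioxide production, L/min (>= 0).
#' @return EE in kcal/min.
#' @export
ee_from_gas_exchange <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    stop_invalid("'vo2' and 'vco2' must be non-negative")
  3.781 * vo2 + 1.237 * vco2
}

#' Construct a gas-exchange series
#'
#' @param time POSIXct timestamps (strictly increasing, UTC).
#' @param vo2,vco2 gas rates in L/min (non-negative, finite).
#' @param heart_rate optional beats/min.
#' @return data frame of class `gas_exchange` with an `ee_kcal_min` column.
#' @export
gas_exchange_series <- function(time, vo2, vco2, heart_rate = NULL) {
  time <- as.POSIXct(time, tz = "UTC")
  if (anyNA(time) || any(diff(as.numeric(time)) <= 0))
    stop_invalid("timestamps must be strictly increasing")
  if (length(vo2) != length(time) || length(vco2) != length(time))
    stop_invalid("'vo2' and 'vco2' must match 'time' in length")
  if (any(!is.finite(vo2)) || any(!is.finite(vco2)) ||
      any(vo2 < 0) || any(vco2 < 0))
    stop_invalid("'vo2' and 'vco2' must be finite and non-negative")
  out <- data.frame(time = time, vo2 = vo2, vco2 = vco2,
                    ee_kcal_min = ee_from_gas_exchange(vo2, vco2))
  if (!is.null(heart_rate)) out$heart_rate <- heart_rate
  class(out) <- c("gas_exchange", "data.frame")
  out
}

# mean of `col` over samples with time in (end - window, end]
window_mean <- function(series, window_end, window_min, col = "ee_kcal_min") {
  t <- as.numeric(series$time)
  e <- as.numeric(as.POSIXct(window_end, tz = "UTC"))
  sel <- t > e - window_min * 60 & t <= e
  if (!any(sel))
    stop_invalid("no samples in window; series covers [",
                 format(series$time[1L]), ", ",
                 format(series$time[nrow(series)]), "]")
  mean(series[[col]][sel])
}

#' Resting energy expenditure from a seated rest period
#'
#' Averages per-sample EE over the final `average_last` minutes of a
#' `total_rest`-minute seated rest (defaults 15 and 5 min): the early
#' portion is discarded so oxygen-uptake kinetics settle before averaging.
#'
#' @param series a `gas_exchange` series starting at the onset of rest.
#' @param total_rest rest period length, minutes.
#' @param average_last trailing window to average, minutes
#'   (`<= total_rest`).
#' @return resting EE, kcal/min.
#' @export
resting_ee <- function(series, total_rest = 15, average_last = 5) {
  if (average_last > total_rest)
    stop_invalid("'average_last' must not exceed 'total_rest'")
  t0 <- as.numeric(series$time[1L])
  span <- as.numeric(series$time[nrow(series)]) - t0
  if (span < total_rest * 60 - 1)
    stop_invalid("series covers only ", round(span / 60, 1),
                 " min; need ", total_rest, " min of rest data")
  window_mean(series, series$time[1L] + total_rest * 60, average_last)
}

#' Steady-state mean over the end of an activity bout
#'
#' Averages a signal over the trailing `averaging_window` minutes of a bout
#' (the window is half-open on the left, closed on the right), the
#' standard way to summarise near-steady-state treadmill bouts. Works on
#' gas-exchange series (mean EE, default) or any timestamped data frame
#' (e.g. per-minute counts with `col = "counts"`).
#'
#' @param series data frame with a POSIXct `time` column.
#' @param start,end bout start and end times.
#' @param averaging_window minutes, anchored at the bout end; must not
#'   exceed the bout duration. Default 2.
#' @param col column to average.
#' @return arithmetic mean of `col` over the window.
#' @export
bout_steady_state_mean <- function(series, start, end, averaging_window = 2,
                                   col = "ee_kcal_min") {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (start >= end) stop_invalid("'start' must precede 'end'")
  if (averaging_window * 60 > as.numeric(end) - as.numeric(start))
    stop_invalid("'averaging_window' exceeds bout duration")
  window_mean(series, end, averaging_window, col)
}
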