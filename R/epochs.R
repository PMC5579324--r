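#' Construct an epoch-level activity count series
#'
#' @param start_time POSIXct start of the first epoch (UTC).
#' @param epoch_duration epoch length in seconds (typically 1 for
#'   laboratory sessions, 10 for free-living, 60 for counts/min).
#' @param counts non-negative counts, one per epoch.
#' @param device_label optional device identifier.
#' @return object of class `epoch_series`.
#' @export
epoch_series <- function(start_time, epoch_duration, counts,
                         device_label = "device") {
  start_time <- as.POSIXct(start_time, tz = "UTC")
  stopifnot(length(start_time) == 1L, length(epoch_duration) == 1L)
  if (epoch_duration <= 0) stop_invalid("'epoch_duration' must be positive")
  if (length(counts) < 1L) stop_invalid("'counts' must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_invalid("'counts' must be finite and non-negative")
  structure(list(start_time = start_time,
                 epoch_duration = as.numeric(epoch_duration),
                 counts = as.numeric(counts),
                 device_label = device_label),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("Epoch series '%s': %d x %gs epochs from %s (%.1f min)\n",
              x$device_label, length(x$counts), x$epoch_duration,
              format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
              length(x$counts) * x$epoch_duration / 60))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch start times of a series
#' @param series an `epoch_series`.
#' @return POSIXct vector, one per epoch.
#' @export
epoch_times <- function(series) {
  series$start_time + (seq_along(series$counts) - 1L) * series$epoch_duration
}

#' Resample an epoch series to counts per minute
#'
#' Aggregates native epochs (1 s or 10 s) to 60-s epochs by summation, the
#' unit the calibration model and cut-points are defined on. A trailing
#' partial minute is dropped with a warning.
#'
#' @param series an `epoch_series` whose `epoch_duration` divides 60.
#' @return an `epoch_series` with `epoch_duration = 60`.
#' @export
resample_to_counts_per_min <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  d <- series$epoch_duration
  if (d == 60) return(series)
  if (60 %% d != 0)
    stop_invalid("unsupported epoch duration ", d, " s: must divide 60")
  per_min <- 60 / d
  n_full <- length(series$counts) %/% per_min
  dropped <- length(series$counts) - n_full * per_min
  if (dropped > 0)
    warning("dropping trailing partial minute (", dropped * d, " s)",
            call. = FALSE)
  if (n_full == 0L) stop_invalid("series shorter than one minute")
  m <- matrix(series$counts[seq_len(n_full * per_min)], nrow = per_min)
  epoch_series(series$start_time, 60, colSums(m), series$device_label)
}

#' Detect nonwear time as prolonged runs of zero counts
#'
#' Flags maximal runs of consecutive zero-count epochs whose duration
#' *strictly exceeds* `run_threshold` minutes as nonwear; shorter zero runs
#' (including runs of exactly the threshold length) are retained as wear.
#' A single nonzero epoch breaks a run. The rule is evaluated on the
#' series' native epochs.
#'
#' @param series an `epoch_series`.
#' @param run_threshold minutes; default 60 (the conventional ">60 min of
#'   continuous zero counts" rule).
#' @return object of class `wear_mask`: per-epoch logical `wear` flags plus
#'   a run-length summary of nonwear intervals.
#' @export
detect_nonwear <- function(series, run_threshold = 60) {
  stopifnot(inherits(series, "epoch_series"))
  r <- rle(series$counts == 0)
  run_min <- r$lengths * series$epoch_duration / 60
  nonwear_run <- r$values & run_min > run_threshold
  wear <- !inverse.rle(list(lengths = r$lengths, values = nonwear_run))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_epoch = starts[nonwear_run],
                     end_epoch = ends[nonwear_run],
                     minutes = run_min[nonwear_run])
  structure(list(wear = wear, runs = runs,
                 epoch_duration = series$epoch_duration,
                 run_threshold = run_threshold),
            class = "wear_mask")
}

#' @export
print.wear_mask <- function(x, ...) {
  cat(sprintf("Wear mask: %.1f wear min, %d nonwear run(s) (> %g min rule)\n",
              sum(x$wear) * x$epoch_duration / 60, nrow(x$runs),
              x$run_threshold))
  invisible(x)
}

#' Wear time in minutes under a mask
#' @param mask a `wear_mask`.
#' @return total wear minutes.
#' @export
wear_minutes <- function(mask) {
  stopifnot(inherits(mask, "wear_mask"))
  sum(mask$wear) * mask$epoch_duration / 60
}

#' Screen a day for sufficient wear time
#'
#' A free-living day enters analysis only with at least `min_wear` minutes
#' of wear time (default 600 min = 10 h, inclusive).
#'
#' @param series an `epoch_series` covering the day.
#' @param mask the matching `wear_mask`.
#' @param min_wear minimum wear minutes; default 600.
#' @return logical with attribute `wear_minutes`.
#' @export
is_valid_day <- function(series, mask, min_wear = 600) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "wear_mask"))
  if (length(mask$wear) != length(series$counts))
    stop_invalid("mask is not aligned to series (lengths ",
                 length(mask$wear), " vs ", length(series$counts), ")")
  wm <- wear_minutes(mask)
  structure(wm >= min_wear, wear_minutes = wm)
}

#' Classify activity intensity from counts per minute
#'
#' Assigns each counts/min value to an intensity category using inclusive
#' lower band edges: with the published cut-points, counts < 1253 are
#' light, 1253-1272 moderate, 1273-6987 hard, and > 6987 very hard.
#' Non-integer values obey the same inequalities (1252.5 is light).
#'
#' @param counts_per_min non-negative counts/min (vectorised).
#' @param thresholds an `intensity_thresholds`; default
#'   [published_thresholds()].
#' @return factor of category labels.
#' @export
classify_intensity <- function(counts_per_min,
                               thresholds = published_thresholds()) {
  stopifnot(inherits(thresholds, "intensity_thresholds"))
  if (any(counts_per_min < 0, na.rm = TRUE))
    stop_invalid("'counts_per_min' must be non-negative")
  idx <- findInterval(counts_per_min, thresholds$boundaries) + 1L
  factor(thresholds$labels[idx], levels = thresholds$labels)
}

#' Daily summary of wear time, intensity, and energy expenditure
#'
#' For each wear minute, predicts EE from the calibration model and
#' classifies intensity; aggregates minutes, mean EE, and total EE per
#' category and overall.
#'
#' @param series an `epoch_series` (any epoch length dividing 60; resampled
#'   to counts/min internally, with the mask resampled alongside: a minute
#'   is wear iff all its native epochs are wear).
#' @param mask `wear_mask` aligned to `series` (on native epochs).
#' @param thresholds `intensity_thresholds`.
#' @param model `ee_calibration` for count-based EE.
#' @param mass_kg participant body mass.
#' @param min_wear valid-day wear threshold (minutes).
#' @param force bypass the valid-day screen.
#' @return list of class `day_summary`: per-category table (`minutes`,
#'   `mean_ee`, `total_ee`), overall totals, wear minutes.
#' @export
summarize_day <- function(series, mask, thresholds = published_thresholds(),
                          model = published_calibration(), mass_kg,
                          min_wear = 600, force = FALSE) {
  valid <- is_valid_day(series, mask, min_wear)
  if (!valid && !force)
    stop_invalid("not a valid day (", attr(valid, "wear_minutes"),
                 " wear min < ", min_wear, "); use force = TRUE to override")
  per_min <- 60 / series$epoch_duration
  cpm <- resample_to_counts_per_min(series)
  n_min <- length(cpm$counts)
  wear_mat <- matrix(mask$wear[seq_len(n_min * per_min)], nrow = per_min)
  minute_wear <- apply(wear_mat, 2L, all)
  cts <- cpm$counts[minute_wear]
  cat_ <- classify_intensity(cts, thresholds)
  ee <- predict_ee(model, cts, mass_kg)
  tab <- data.frame(
    category = factor(thresholds$labels, levels = thresholds$labels),
    minutes = as.vector(table(cat_)),
    mean_ee = as.vector(tapply(ee, cat_, mean, default = NA_real_)),
    total_ee = as.vector(tapply(ee, cat_, sum, default = 0)))
  structure(list(by_category = tab,
                 wear_minutes = sum(minute_wear),
                 total_ee = sum(ee),
                 mean_ee = mean(ee)),
            class = "day_summary")
}

#' @export
print.day_summary <- function(x, ...) {
  cat(sprintf("Daily summary: %d wear min, total EE %.1f kcal\n",
              x$wear_minutes, x$total_ee))
  print(x$by_category, row.names = FALSE)
  invisible(x)
}
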