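#' Bin GPS fixes by reported accuracy radius
#'
#' Partitions fixes into the accuracy bins {<=25, 26-50, 51-75, 76-100,
#' > 100 m} (the radius within which the true position lies with 68%
#' probability) and reports per-bin counts, percentages, and median radii.
#'
#' @param fixes data frame with an `accuracy` column (metres, > 0).
#' @return data frame (`bin`, `n`, `pct`, `median_accuracy`) with attribute
#'   `overall_median`; empty input gives a zero-count table.
#' @export
bin_accuracy <- function(fixes) {
  labs <- c("<=25", "26-50", "51-75", "76-100", ">100")
  if (is.null(fixes) || nrow(fixes) == 0L) {
    out <- data.frame(bin = labs, n = 0L, pct = NA_real_,
                      median_accuracy = NA_real_)
    attr(out, "overall_median") <- NA_real_
    return(out)
  }
  acc <- fixes$accuracy
  if (any(acc <= 0 | !is.finite(acc)))
    stop_invalid("'accuracy' must be positive and finite")
  bin <- cut(acc, breaks = c(-Inf, 25, 50, 75, 100, Inf), labels = labs)
  med <- tapply(acc, bin, stats::median)
  out <- data.frame(bin = labs,
                    n = as.vector(table(bin)),
                    pct = as.vector(table(bin)) / length(acc) * 100,
                    median_accuracy = as.vector(med))
  attr(out, "overall_median") <- stats::median(acc)
  out
}

#' Fraction of fixes with acceptable accuracy
#'
#' @param fixes data frame with an `accuracy` column.
#' @param threshold acceptability limit in metres (default 50).
#' @return proportion of fixes with `accuracy <= threshold`.
#' @export
acceptable_fraction <- function(fixes, threshold = 50) {
  if (nrow(fixes) == 0L) stop_invalid("'fixes' is empty")
  mean(fixes$accuracy <= threshold)
}

EARTH_RADIUS_M <- 6371000

#' Project GPS fixes to local planar coordinates
#'
#' Equirectangular projection centred on the track centroid:
#' `x = R * dlon * cos(lat0)`, `y = R * dlat` (angles in radians,
#' R = 6371000 m). Adequate at city scale (< 0.5% length error for tracks
#' under ~20 km below 60 degrees latitude); refuses pole-adjacent tracks.
#'
#' @param fixes data frame with `lat`, `lon` columns.
#' @param center optional `c(lat0, lon0)` overriding the centroid.
#' @return data frame of `x`, `y` in metres (other columns preserved),
#'   with attribute `center`.
#' @seealso [local_to_latlon()] for the inverse.
#' @export
project_to_local <- function(fixes, center = NULL) {
  if (nrow(fixes) == 0L) stop_invalid("'fixes' is empty")
  center <- center %||% c(mean(fixes$lat), mean(fixes$lon))
  if (abs(center[1L]) > 85)
    stop_invalid("unsupported region: projection centre within 5 degrees ",
                 "of a pole")
  rad <- pi / 180
  out <- fixes
  out$x <- EARTH_RADIUS_M * (fixes$lon - center[2L]) * rad * cos(center[1L] * rad)
  out$y <- EARTH_RADIUS_M * (fixes$lat - center[1L]) * rad
  attr(out, "center") <- center
  out
}

#' Inverse of the local planar projection
#'
#' @param xy data frame with `x`, `y` columns (metres).
#' @param center `c(lat0, lon0)` used in the forward projection.
#' @return data frame with `lat`, `lon` columns restored.
#' @export
local_to_latlon <- function(xy, center) {
  rad <- pi / 180
  out <- xy
  out$lat <- center[1L] + xy$y / (EARTH_RADIUS_M * rad)
  out$lon <- center[2L] + xy$x / (EARTH_RADIUS_M * rad * cos(center[1L] * rad))
  out
}

#' Interpolate a straight-segment path through sequential fixes
#'
#' Connects consecutive projected fixes with straight segments and derives
#' per-segment geometry: planar length, elapsed time, implied speed, and
#' bearing.
#'
#' @param fixes data frame with `time`, `lat`, `lon` (>= 2 rows, strictly
#'   increasing timestamps).
#' @return data frame of segments: `x0, y0, x1, y1, t0, t1, length_m,
#'   dt_s, speed_ms, bearing_deg`, with the projection `center` attribute.
#' @export
interpolate_path <- function(fixes) {
  if (nrow(fixes) < 2L) stop_invalid("need at least 2 fixes")
  t <- as.numeric(as.POSIXct(fixes$time, tz = "UTC"))
  if (any(diff(t) == 0))
    stop_invalid("duplicate timestamps at rows: ",
                 paste(which(diff(t) == 0) + 1L, collapse = ", "))
  if (any(diff(t) < 0)) stop_invalid("timestamps must be increasing")
  p <- project_to_local(fixes)
  n <- nrow(p)
  i <- seq_len(n - 1L)
  dx <- p$x[i + 1L] - p$x[i]; dy <- p$y[i + 1L] - p$y[i]
  len <- sqrt(dx^2 + dy^2)
  out <- data.frame(x0 = p$x[i], y0 = p$y[i], x1 = p$x[i + 1L],
                    y1 = p$y[i + 1L], t0 = t[i], t1 = t[i + 1L],
                    length_m = len, dt_s = diff(t),
                    speed_ms = len / diff(t),
                    bearing_deg = (atan2(dx, dy) * 180 / pi) %% 360)
  attr(out, "center") <- attr(p, "center")
  out
}

# turning angle (deg, 0 = straight ahead) at each interior vertex
turning_angles <- function(x, y) {
  n <- length(x)
  ang <- rep(NA_real_, n)
  if (n < 3L) return(ang)
  for (i in 2:(n - 1L)) {
    v1 <- c(x[i] - x[i - 1L], y[i] - y[i - 1L])
    v2 <- c(x[i + 1L] - x[i], y[i + 1L] - y[i])
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) { ang[i] <- 0; next }
    cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
    ang[i] <- acos(cosang) * 180 / pi
  }
  ang
}

#' Flag likely-erroneous GPS fixes
#'
#' A fix is suspect when it deviates sharply from its neighbours over a
#' short time: either both its incoming and outgoing implied speeds exceed
#' `max_speed`, or its turning angle exceeds `min_turn` *and* the detour
#' ratio `(d_in + d_out) / d_skip` exceeds `min_detour_ratio` (d_skip is
#' the direct distance between its neighbours). Endpoints are never
#' flagged. A genuine street corner at walking speed (turn ~90 degrees,
#' detour ratio ~1.4) survives the defaults; a multi-km spike does not.
#'
#' @param fixes data frame with `time`, `lat`, `lon` (>= 3 rows).
#' @param max_speed m/s; default 40.
#' @param min_turn degrees (0 = straight ahead); default 120.
#' @param min_detour_ratio dimensionless; default 3.
#' @return logical vector, one flag per fix.
#' @export
flag_suspect_fixes <- function(fixes, max_speed = 40, min_turn = 120,
                               min_detour_ratio = 3) {
  if (nrow(fixes) < 3L) stop_invalid("need at least 3 fixes")
  t <- as.numeric(as.POSIXct(fixes$time, tz = "UTC"))
  p <- project_to_local(fixes)
  n <- nrow(p)
  d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  v <- d / diff(t)
  turn <- turning_angles(p$x, p$y)
  suspect <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    speed_rule <- v[i - 1L] > max_speed && v[i] > max_speed
    d_skip <- sqrt((p$x[i + 1L] - p$x[i - 1L])^2 +
                     (p$y[i + 1L] - p$y[i - 1L])^2)
    detour <- if (d_skip == 0) Inf else (d[i - 1L] + d[i]) / d_skip
    turn_rule <- !is.na(turn[i]) && turn[i] > min_turn &&
      detour > min_detour_ratio
    suspect[i] <- speed_rule || turn_rule
  }
  suspect
}

#' Build an intensity-annotated space-time trajectory
#'
#' Fuses a GPS fix log with an epoch count series into a time-geography
#' "space-time cube" polyline: vertices are projected fix positions with
#' elapsed time on the vertical axis; each segment carries the dominant
#' activity-intensity category of the wear minutes it spans (shading in a
#' rendered figure), and vertices with accuracy radius > 50 m carry a
#' low-accuracy marker.
#'
#' @param fixes data frame: `time`, `lat`, `lon`, `accuracy`.
#' @param series an `epoch_series` overlapping the fixes in time.
#' @param thresholds `intensity_thresholds` for classification.
#' @param model `ee_calibration` (reserved for EE-weighted variants;
#'   classification itself uses counts).
#' @param mass_kg participant body mass.
#' @param mask optional `wear_mask` on the native series; computed with
#'   [detect_nonwear()] defaults when omitted.
#' @param low_accuracy_threshold metres; default 50.
#' @return object of class `space_time_trajectory`: `vertices`
#'   (`x, y, t, time, intensity, low_accuracy`), `segments` (`length_m,
#'   dt_s, speed_ms, turn_deg, intensity, inherited, suspect`), and the
#'   projection centre.
#' @export
build_space_time_trajectory <- function(fixes, series,
                                        thresholds = published_thresholds(),
                                        model = published_calibration(),
                                        mass_kg = 70.5, mask = NULL,
                                        low_accuracy_threshold = 50) {
  stopifnot(inherits(series, "epoch_series"))
  if (nrow(fixes) < 2L) stop_invalid("need at least 2 fixes")
  ft <- as.numeric(as.POSIXct(fixes$time, tz = "UTC"))
  if (any(diff(ft) <= 0)) stop_invalid("fix timestamps must be strictly increasing")
  mask <- mask %||% detect_nonwear(series)
  per_min <- 60 / series$epoch_duration
  cpm <- suppressWarnings(resample_to_counts_per_min(series))
  n_min <- length(cpm$counts)
  wear_mat <- matrix(mask$wear[seq_len(n_min * per_min)], nrow = per_min)
  minute_wear <- apply(wear_mat, 2L, all)
  minute_t <- as.numeric(epoch_times(cpm))
  series_end <- minute_t[n_min] + 60
  if (ft[length(ft)] < minute_t[1L] || ft[1L] > series_end)
    stop_invalid("fixes and epoch series do not overlap in time")
  minute_cat <- classify_intensity(cpm$counts, thresholds)
  p <- project_to_local(fixes)
  seg_cat <- character(nrow(fixes) - 1L)
  inherited <- logical(nrow(fixes) - 1L)
  prev <- NA_character_
  for (i in seq_len(nrow(fixes) - 1L)) {
    in_span <- minute_t >= ft[i] & minute_t < ft[i + 1L] & minute_wear
    if (any(in_span)) {
      cats <- minute_cat[in_span]
      tab <- table(cats)
      top <- names(tab)[tab == max(tab)]
      # ties break toward the higher intensity
      seg_cat[i] <- top[length(top)]
      prev <- seg_cat[i]
    } else {
      seg_cat[i] <- prev
      inherited[i] <- TRUE
    }
  }
  # a leading segment with no wear minutes inherits forward
  if (anyNA(seg_cat)) {
    first_ok <- which(!is.na(seg_cat))[1L]
    if (is.na(first_ok)) stop_invalid("no wear minutes overlap the track")
    seg_cat[seq_len(first_ok - 1L)] <- seg_cat[first_ok]
  }
  t_rel <- ft - ft[1L]
  vert_cat <- c(seg_cat, seg_cat[length(seg_cat)])
  vertices <- data.frame(
    x = p$x, y = p$y, t = t_rel,
    time = as.POSIXct(ft, tz = "UTC", origin = "1970-01-01"),
    intensity = factor(vert_cat, levels = thresholds$labels),
    low_accuracy = fixes$accuracy > low_accuracy_threshold)
  i <- seq_len(nrow(fixes) - 1L)
  len <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  segments <- data.frame(
    length_m = len, dt_s = diff(ft), speed_ms = len / diff(ft),
    turn_deg = turning_angles(p$x, p$y)[i + 1L],
    intensity = factor(seg_cat, levels = thresholds$labels),
    inherited = inherited,
    suspect = if (nrow(fixes) >= 3L) flag_suspect_fixes(fixes)[i + 1L]
              else rep(FALSE, length(i)))
  structure(list(vertices = vertices, segments = segments,
                 center = attr(p, "center")),
            class = "space_time_trajectory")
}

#' @export
print.space_time_trajectory <- function(x, ...) {
  cat(sprintf("Space-time trajectory: %d vertices, %.2f km, %.1f min\n",
              nrow(x$vertices), sum(x$segments$length_m) / 1000,
              max(x$vertices$t) / 60))
  print(table(x$segments$intensity))
  invisible(x)
}

#' @export
plot.space_time_trajectory <- function(x, ...) {
  shade <- grDevices::gray(seq(0.8, 0, length.out = nlevels(x$segments$intensity)))
  graphics::plot(x$vertices$x, x$vertices$y, type = "n", asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = "Movement path (dark = higher intensity)", ...)
  v <- x$vertices
  graphics::segments(v$x[-nrow(v)], v$y[-nrow(v)], v$x[-1L], v$y[-1L],
                     col = shade[as.integer(x$segments$intensity)], lwd = 2)
  graphics::points(v$x[v$low_accuracy], v$y[v$low_accuracy],
                   col = "orange", pch = 19)
  invisible(x)
}
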