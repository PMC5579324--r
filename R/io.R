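#' Read and write epoch-level count files
#'
#' Epoch files are delimiter-separated text with columns `timestamp`
#' (ISO 8601 UTC) and `counts`, optionally preceded by a skippable metadata
#' header block (the common actigraph export dialect: serial number, start
#' time, epoch length, ...).
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param skip metadata header lines to skip (default 0).
#' @param device_label device identifier for the resulting series.
#' @return an `epoch_series` (epoch duration inferred from the first two
#'   timestamps).
#' @export
read_epoch_file <- function(path, sep = ",", skip = 0, device_label = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                         stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(d)))
    stop_invalid("epoch file needs 'timestamp' and 'counts' columns")
  ts <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (nrow(d) < 2L) stop_invalid("epoch file needs at least 2 rows")
  epoch_series(ts[1L], as.numeric(diff(ts[1:2])), d$counts,
               device_label %||% basename(path))
}

#' @rdname read_epoch_file
#' @param series an `epoch_series` to write.
#' @export
write_epoch_file <- function(series, path, sep = ",") {
  d <- data.frame(timestamp = format(epoch_times(series),
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                  counts = series$counts)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gas-exchange files
#'
#' Delimiter-separated text with columns `timestamp`, `vo2`, `vco2`
#' (L/min), optionally `heart_rate`.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return a `gas_exchange` series.
#' @export
read_gas_exchange_file <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("timestamp", "vo2", "vco2") %in% names(d)))
    stop_invalid("gas-exchange file needs 'timestamp', 'vo2', 'vco2'")
  ts <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  gas_exchange_series(ts, d$vo2, d$vco2, heart_rate = d$heart_rate)
}

#' @rdname read_gas_exchange_file
#' @param series a `gas_exchange` series to write.
#' @export
write_gas_exchange_file <- function(series, path, sep = ",") {
  d <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"),
                  vo2 = series$vo2, vco2 = series$vco2)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GPS fix tables
#'
#' Delimiter-separated text with columns `timestamp`, `lat`, `lon`,
#' `accuracy` (metres).
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return data frame of fixes (`time`, `lat`, `lon`, `accuracy`).
#' @export
read_gps_fixes <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("timestamp", "lat", "lon", "accuracy")
  if (!all(req %in% names(d)))
    stop_invalid("fix table needs columns ", paste(req, collapse = ", "))
  data.frame(time = as.POSIXct(d$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S")),
             lat = d$lat, lon = d$lon, accuracy = d$accuracy)
}

#' @rdname read_gps_fixes
#' @param fixes data frame of fixes to write.
#' @export
write_gps_fixes <- function(fixes, path, sep = ",") {
  d <- data.frame(timestamp = format(fixes$time, "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"),
                  lat = fixes$lat, lon = fixes$lon, accuracy = fixes$accuracy)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GPX 1.1 tracks
#'
#' Round-trips GPS fixes through GPX 1.1. The accuracy radius is stored in
#' each track point's `<extensions><accuracy>` element (GPX itself has no
#' accuracy field).
#'
#' @param path file path.
#' @return data frame of fixes (`time`, `lat`, `lon`, `accuracy`; accuracy
#'   NA when absent from the file).
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0L) stop_invalid("no track points in GPX file")
  get1 <- function(pt, xp) {
    node <- xml2::xml_find_first(pt, xp)
    if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
  }
  data.frame(
    time = as.POSIXct(vapply(pts, get1, "", "./time"),
                      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    accuracy = as.numeric(vapply(pts, get1, "", "./extensions/accuracy")))
}

#' @rdname read_gpx
#' @param fixes data frame of fixes to write.
#' @param creator GPX creator attribute.
#' @export
write_gpx <- function(fixes, path, creator = "eecalib") {
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = creator,
    xmlns = "http://www.topografix.com/GPX/1/1")
  trkseg <- xml2::xml_add_child(xml2::xml_add_child(doc, "trk"), "trkseg")
  for (i in seq_len(nrow(fixes))) {
    pt <- xml2::xml_add_child(trkseg, "trkpt",
                              lat = format(fixes$lat[i], digits = 10),
                              lon = format(fixes$lon[i], digits = 10))
    xml2::xml_add_child(pt, "time",
                        format(fixes$time[i], "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC"))
    if (!is.null(fixes$accuracy))
      xml2::xml_add_child(xml2::xml_add_child(pt, "extensions"),
                          "accuracy", format(fixes$accuracy[i], digits = 8))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a trajectory as GeoJSON
#'
#' Writes a `space_time_trajectory` (or plain fix table) as a GeoJSON
#' LineString whose properties carry per-vertex elapsed time, intensity
#' category, and low-accuracy markers.
#'
#' @param x a `space_time_trajectory` or a data frame with `lon`, `lat`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_geojson <- function(x, path) {
  if (inherits(x, "space_time_trajectory")) {
    ll <- local_to_latlon(x$vertices, x$center)
    coords <- unname(Map(c, ll$lon, ll$lat))
    props <- list(t = x$vertices$t,
                  intensity = as.character(x$vertices$intensity),
                  low_accuracy = x$vertices$low_accuracy)
  } else {
    coords <- unname(Map(c, x$lon, x$lat))
    props <- list()
  }
  gj <- list(type = "FeatureCollection",
             features = list(list(
               type = "Feature",
               geometry = list(type = "LineString", coordinates = coords),
               properties = props)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
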