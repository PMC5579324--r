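test_that("accuracy binning partitions fixes with printed bin edges", {
  f <- data.frame(accuracy = c(10, 30, 60, 90, 150))
  b <- bin_accuracy(f)
  expect_equal(b$n, rep(1L, 5))
  # integer boundary semantics: 25 in first bin, 26 in second
  b2 <- bin_accuracy(data.frame(accuracy = c(25, 26)))
  expect_equal(b2$n, c(1L, 1L, 0L, 0L, 0L))
  b3 <- bin_accuracy(data.frame(accuracy = rep(30, 7)))
  expect_equal(b3$n[2], 7L)
  expect_equal(b3$median_accuracy[2], 30)
  expect_equal(attr(b3, "overall_median"), 30)
  # partition property on a generated mixed set
  set.seed(3)
  fm <- data.frame(accuracy = exp(runif(500, log(5), log(5000))))
  bm <- bin_accuracy(fm)
  expect_equal(sum(bm$n), 500L)
  expect_equal(sum(bm$pct), 100)
  # empty input: empty report, not an error
  be <- bin_accuracy(data.frame(accuracy = numeric(0)))
  expect_equal(sum(be$n), 0L)
})

test_that("acceptable fraction counts fixes at or under the threshold", {
  expect_equal(acceptable_fraction(data.frame(accuracy = rep(10, 4))), 1)
  expect_equal(acceptable_fraction(data.frame(accuracy = c(10, 100))), 0.5)
  expect_equal(acceptable_fraction(data.frame(accuracy = c(50, 50.1))), 0.5)
  # generator configured near the field-observed 72.7% within binomial bounds
  base_t <- as.POSIXct("2017-01-02 08:00:00", tz = "UTC")
  wp <- data.frame(lat = c(53, 53.4), lon = c(-6.25, -6.25),
                   time = base_t + c(0, 761 * 60))
  cfg <- sim_config(gps_outlier_fraction = 0.176,
                    gps_bin_probs = c(0.323, 0.403, 0.038, 0.059))
  g <- generate_gps_track(wp, cfg, seed = 13)
  p_target <- (0.323 + 0.403) / (0.323 + 0.403 + 0.038 + 0.059) * (1 - 0.176)
  expect_lt(abs(acceptable_fraction(g) - p_target),
            2.576 * sqrt(p_target * (1 - p_target) / nrow(g)))
})

test_that("local projection has metre-true axes and an exact inverse", {
  f <- data.frame(lat = c(53, 53.001), lon = c(-6.25, -6.25))
  p <- project_to_local(f, center = c(53, -6.25))
  expect_equal(p$x, c(0, 0))
  expect_equal(p$y[2], 6371000 * 0.001 * pi / 180, tolerance = 1e-9)  # 111.19 m
  expect_equal(p$y[2], 111.19, tolerance = 1e-4)
  # centroid maps to the origin
  f2 <- data.frame(lat = 53 + c(-0.01, 0.01), lon = -6.25 + c(-0.02, 0.02))
  p2 <- project_to_local(f2)
  expect_equal(mean(p2$x), 0, tolerance = 1e-9)
  expect_equal(mean(p2$y), 0, tolerance = 1e-9)
  # round trip to within 1e-9 degrees
  back <- local_to_latlon(p2, attr(p2, "center"))
  expect_equal(back$lat, f2$lat, tolerance = 1e-9)
  expect_equal(back$lon, f2$lon, tolerance = 1e-9)
  expect_error(project_to_local(data.frame(lat = 89, lon = 0)), "pole")
})

test_that("projected distances stay within 0.5% of great-circle distances", {
  # city-scale tracks below 60 degrees latitude
  haversine <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    a <- sin((lat2 - lat1) * r / 2)^2 +
      cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
    2 * 6371000 * asin(sqrt(a))
  }
  set.seed(8)
  for (lat0 in c(0, 35, 59)) {
    f <- data.frame(lat = lat0 + runif(10, -0.05, 0.05),
                    lon = 10 + runif(10, -0.08, 0.08))
    p <- project_to_local(f)
    for (i in 1:9) {
      d_proj <- sqrt((p$x[i + 1] - p$x[i])^2 + (p$y[i + 1] - p$y[i])^2)
      d_true <- haversine(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1])
      if (d_true > 1) expect_lt(abs(d_proj - d_true) / d_true, 0.005)
    }
  }
})

test_that("path interpolation computes segment geometry", {
  mdeg <- 6371000 * pi / 180
  f <- data.frame(time = t0() + c(0, 100),
                  lat = c(53, 53 + 100 / mdeg), lon = -6.25)
  seg <- interpolate_path(f)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_m, 100, tolerance = 1e-6)
  expect_equal(seg$speed_ms, 1, tolerance = 1e-6)
  # collinear equally spaced fixes: total length = endpoint distance
  fc <- walking_fixes(n = 11, spacing_m = 50)
  segc <- interpolate_path(fc)
  expect_equal(sum(segc$length_m),
               sqrt(diff(range(project_to_local(fc)$y))^2), tolerance = 1e-6)
  expect_error(interpolate_path(fc[1, ]), "at least 2")
  fd <- fc; fd$time[3] <- fd$time[2]
  expect_error(interpolate_path(fd), "duplicate")
})

test_that("path length is invariant under rotation and time translation", {
  set.seed(14)
  f <- walking_fixes(n = 15, spacing_m = 80)
  f$lon <- f$lon + cumsum(rnorm(15, 0, 1e-4))
  len0 <- sum(interpolate_path(f)$length_m)
  # rigid rotation of projected coordinates preserves length
  p <- project_to_local(f)
  th <- 0.7
  rx <- p$x * cos(th) - p$y * sin(th)
  ry <- p$x * sin(th) + p$y * cos(th)
  len_rot <- sum(sqrt(diff(rx)^2 + diff(ry)^2))
  expect_equal(len_rot, len0, tolerance = 1e-9)
  f2 <- f; f2$time <- f$time + 86400
  expect_equal(sum(interpolate_path(f2)$length_m), len0)
})

test_that("suspect-fix flagging isolates spikes but spares street corners", {
  # straight constant-speed track: no flags
  f <- walking_fixes(n = 20)
  expect_false(any(flag_suspect_fixes(f)))
  # one fix displaced 5 km off a 100-m-spaced walking track
  fo <- f
  fo$lon[10] <- fo$lon[10] + 5000 / (6371000 * pi / 180 * cos(53 * pi / 180))
  flags <- flag_suspect_fixes(fo)
  expect_true(flags[10])
  expect_equal(which(flags), 10L)
  # genuine 90-degree street corner at walking speed: not flagged
  mdeg <- 6371000 * pi / 180
  n <- 21
  corner <- data.frame(time = t0() + (seq_len(n) - 1) * 60,
                       lat = 53, lon = -6.25, accuracy = 10)
  for (i in 2:n) {
    if (i <= 11) corner$lat[i] <- corner$lat[i - 1] + 100 / mdeg
    else corner$lon[i] <- corner$lon[i - 1] +
        100 / (mdeg * cos(53 * pi / 180))
    if (i > 11) corner$lat[i] <- corner$lat[11]
  }
  expect_false(any(flag_suspect_fixes(corner)))
  # idempotence: removing the flagged fix leaves nothing new to flag
  clean <- fo[!flags, ]
  expect_false(any(flag_suspect_fixes(clean)))
  expect_error(flag_suspect_fixes(f[1:2, ]), "at least 3")
})

test_that("space-time trajectories annotate segments with wear intensity", {
  # stationary fixes + all-light epochs -> vertical line, all light
  day <- epoch_series(as.POSIXct("2017-01-02 00:00:00", tz = "UTC"),
                      10, rep(50, 8640))  # 300 counts/min -> light
  fixes <- data.frame(time = as.POSIXct("2017-01-02 10:00:00", tz = "UTC") +
                        c(0, 1800, 3600),
                      lat = 53, lon = -6.25, accuracy = c(10, 20, 80))
  tr <- build_space_time_trajectory(fixes, day)
  expect_s3_class(tr, "space_time_trajectory")
  expect_equal(nrow(tr$vertices), 3)
  expect_true(all(diff(tr$vertices$t) > 0))
  expect_equal(sum(tr$segments$length_m), 0)
  expect_true(all(tr$segments$intensity == "light"))
  expect_equal(tr$vertices$low_accuracy, c(FALSE, FALSE, TRUE))
  # constructed commute: quiet midday, vigorous evening travel
  counts <- rep(50, 8640)
  evening <- (17 * 360 + 1):(18 * 360)  # 17:00-18:00 at 10-s epochs
  counts[evening] <- 1500               # 9000 counts/min -> very hard
  day2 <- epoch_series(as.POSIXct("2017-01-02 00:00:00", tz = "UTC"), 10, counts)
  mdeg <- 6371000 * pi / 180
  ft <- as.POSIXct("2017-01-02 12:00:00", tz = "UTC") +
    c(0, 3600, 7200, 5 * 3600, 5 * 3600 + 600, 5 * 3600 + 1200)
  fx <- data.frame(time = ft, lat = c(53, 53, 53, 53, 53 + 800 / mdeg,
                                      53 + 1600 / mdeg),
                   lon = -6.25, accuracy = 20)
  tr2 <- build_space_time_trajectory(fx, day2)
  expect_equal(as.character(tail(tr2$segments$intensity, 2)),
               c("very hard", "very hard"))
  expect_true(all(tr2$segments$intensity[1:2] == "light"))
  # vertex count equals fix count; no temporal overlap errors out
  expect_equal(nrow(tr2$vertices), nrow(fx))
  off <- fx; off$time <- off$time + 10 * 86400
  expect_error(build_space_time_trajectory(off, day2), "overlap")
})

test_that("GPS IO round-trips through delimited text, GPX, and GeoJSON", {
  f <- walking_fixes(n = 5)
  f$accuracy <- c(10, 20, 30, 60, 120)
  csv <- tempfile(fileext = ".csv")
  write_gps_fixes(f, csv)
  r <- read_gps_fixes(csv)
  expect_equal(r$lat, f$lat, tolerance = 1e-7)
  expect_equal(r$time, f$time)
  gpx <- tempfile(fileext = ".gpx")
  write_gpx(f, gpx)
  rg <- read_gpx(gpx)
  expect_equal(rg$lat, f$lat, tolerance = 1e-9)
  expect_equal(rg$lon, f$lon, tolerance = 1e-9)
  expect_equal(rg$time, f$time)
  expect_equal(rg$accuracy, f$accuracy, tolerance = 1e-6)
  day <- epoch_series(as.POSIXct("2017-01-01 08:50:00", tz = "UTC"),
                      10, rep(50, 600))
  tr <- build_space_time_trajectory(f, day)
  gj <- tempfile(fileext = ".geojson")
  write_geojson(tr, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  coords <- parsed$features[[1]]$geometry$coordinates
  expect_length(coords, 5)
  expect_equal(coords[[1]][[2]], f$lat[1], tolerance = 1e-9)
  unlink(c(csv, gpx, gj))
})
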