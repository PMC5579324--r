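#' Laboratory treadmill protocol definition
#'
#' @param rest_duration seated rest before the first bout, minutes (> 0).
#' @param bouts data frame with columns `speed` (km/h, >= 0) and
#'   `duration` (minutes, > 0), in bout order.
#' @param recovery_duration passive recovery between bouts, minutes (> 0).
#' @return object of class `lab_protocol`.
#' @export
lab_protocol <- function(rest_duration, bouts, recovery_duration) {
  bouts <- as.data.frame(bouts)
  if (!all(c("speed", "duration") %in% names(bouts)))
    stop_invalid("'bouts' needs columns 'speed' and 'duration'")
  if (nrow(bouts) < 1L) stop_invalid("'bouts' must be non-empty")
  if (rest_duration <= 0 || recovery_duration <= 0 || any(bouts$duration <= 0))
    stop_invalid("all durations must be positive")
  if (any(bouts$speed < 0)) stop_invalid("speeds must be non-negative")
  structure(list(rest_duration = rest_duration, bouts = bouts,
                 recovery_duration = recovery_duration),
            class = "lab_protocol")
}

#' Standard treadmill validation protocols
#'
#' `phase1_protocol()`: 15-min seated rest, then 5-min bouts at 4, 6, 10,
#' and 12 km/h separated by 3-min passive recoveries (light to vigorous
#' intensities). `phase2_protocol()`: three 6-min walking bouts at 4, 5,
#' and 6 km/h separated by 2-min recoveries, preceded by a 5-min rest.
#'
#' @return a `lab_protocol`.
#' @export
phase1_protocol <- function() {
  lab_protocol(15, data.frame(speed = c(4, 6, 10, 12), duration = 5), 3)
}

#' @rdname phase1_protocol
#' @export
phase2_protocol <- function() {
  lab_protocol(5, data.frame(speed = c(4, 5, 6), duration = 6), 2)
}

#' Simulation configuration for the synthetic-data generators
#'
#' Houses every tunable of the generators' stated world. Defaults: residual
#' EE noise 1.94 kcal/min (the calibration SEE); oxygen-uptake on-kinetics
#' time constant 35 s (typical adult value for moderate exercise); linear
#' counts-vs-speed slope 1000 counts/min per km/h with 15% lognormal
#' multiplicative noise; GPS accuracy-radius bins drawn with the observed
#' field proportions and a 17.6% gross-outlier (> 100 m) fraction.
#'
#' @param seed integer seed used by generators when none is passed
#'   explicitly.
#' @param residual_sd additive Gaussian EE noise, kcal/min.
#' @param vo2_time_constant first-order VO2 on-kinetics time constant, s.
#' @param counts_per_kmh counts/min generated per km/h of treadmill speed.
#' @param counts_noise_cv coefficient of variation of multiplicative
#'   lognormal count noise.
#' @param vo2_noise_cv measurement noise CV on simulated gas exchange.
#' @param nonwear_blocks list of `c(start_min, duration_min)` device-off
#'   blocks within the 24-h day (both devices zero).
#' @param noncarry_blocks list of `c(start_min, duration_min)` phone
#'   noncarry blocks (phone zero, reference active).
#' @param phone_scale multiplicative scale mismatch of phone vs reference
#'   counts outside blocks.
#' @param gps_outlier_fraction fraction of GPS fixes that are gross
#'   outliers (accuracy radius > 100 m with large displacement).
#' @param gps_bin_probs probabilities of the four "good" accuracy bins
#'   (<=25, 26-50, 51-75, 76-100 m), renormalised internally.
#' @param gps_noise_scale multiplier on positional noise (0 disables it).
#' @param model the `ee_calibration` used as generating truth.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       residual_sd = 1.94,
                       vo2_time_constant = 35,
                       counts_per_kmh = 1000,
                       counts_noise_cv = 0.15,
                       vo2_noise_cv = 0.03,
                       nonwear_blocks = list(),
                       noncarry_blocks = list(),
                       phone_scale = 1.05,
                       gps_outlier_fraction = 0.176,
                       gps_bin_probs = c(0.323, 0.403, 0.038, 0.059),
                       gps_noise_scale = 1,
                       model = published_calibration()) {
  if (residual_sd < 0) stop_invalid("'residual_sd' must be >= 0")
  if (vo2_time_constant <= 0) stop_invalid("'vo2_time_constant' must be > 0")
  if (counts_per_kmh <= 0) stop_invalid("'counts_per_kmh' must be > 0")
  check_blocks <- function(blocks, what) {
    if (!length(blocks)) return(invisible())
    b <- do.call(rbind, lapply(blocks, function(x) c(x[1L], x[2L])))
    if (any(b[, 1L] < 0) || any(b[, 1L] + b[, 2L] > 1440) || any(b[, 2L] <= 0))
      stop_invalid(what, " block outside the 24-h day")
    o <- order(b[, 1L])
    s <- b[o, 1L]; e <- s + b[o, 2L]
    if (any(s[-1L] < e[-length(e)]))
      stop_invalid(what, " blocks overlap")
  }
  check_blocks(nonwear_blocks, "nonwear")
  check_blocks(noncarry_blocks, "noncarry")
  structure(list(seed = as.integer(seed), residual_sd = residual_sd,
                 vo2_time_constant = vo2_time_constant,
                 counts_per_kmh = counts_per_kmh,
                 counts_noise_cv = counts_noise_cv,
                 vo2_noise_cv = vo2_noise_cv,
                 nonwear_blocks = nonwear_blocks,
                 noncarry_blocks = noncarry_blocks,
                 phone_scale = phone_scale,
                 gps_outlier_fraction = gps_outlier_fraction,
                 gps_bin_probs = gps_bin_probs,
                 gps_noise_scale = gps_noise_scale,
                 model = model),
            class = "sim_config")
}

#' Generate a synthetic calibration dataset
#'
#' Draws counts uniformly on [0, 15000] counts/min and body mass from a
#' Gaussian (mean 70 kg, SD 12, truncated at 40 kg), then sets
#' `ee = predict_ee(true_model, counts, mass) + N(0, residual_sd)` —
#' homoscedastic additive noise matching a single reported SEE.
#'
#' @param n number of observations (>= 3... a later 3-parameter fit needs
#'   at least 4, so `n >= 3` is enforced here and `n >= 4` at fit time).
#' @param true_model generating `ee_calibration`.
#' @param residual_sd Gaussian residual SD, kcal/min (>= 0).
#' @param seed integer seed; fixed seed gives bit-identical tables.
#' @return data frame (`counts_per_min`, `mass_kg`, `ee_kcal_min`).
#' @export
generate_calibration_dataset <- function(n, true_model = published_calibration(),
                                         residual_sd = 1.94, seed = 1L) {
  if (n < 3L) stop_invalid("'n' must be at least 3")
  if (residual_sd < 0) stop_invalid("'residual_sd' must be >= 0")
  stopifnot(inherits(true_model, "ee_calibration"))
  with_seed(seed, {
    counts <- stats::runif(n, 0, 15000)
    mass <- stats::rnorm(n, 70, 12)
    while (any(bad <- mass < 40)) mass[bad] <- stats::rnorm(sum(bad), 70, 12)
    ee <- predict_ee(true_model, counts, mass) +
      stats::rnorm(n, 0, residual_sd)
    data.frame(counts_per_min = counts, mass_kg = mass, ee_kcal_min = ee)
  })
}

# protocol -> per-second segment table (speed, label)
protocol_timeline <- function(protocol) {
  segs <- data.frame(speed = 0, duration = protocol$rest_duration,
                     label = "rest")
  nb <- nrow(protocol$bouts)
  for (i in seq_len(nb)) {
    segs <- rbind(segs, data.frame(speed = protocol$bouts$speed[i],
                                   duration = protocol$bouts$duration[i],
                                   label = sprintf("%g km/h",
                                                   protocol$bouts$speed[i])))
    if (i < nb)
      segs <- rbind(segs, data.frame(speed = 0,
                                     duration = protocol$recovery_duration,
                                     label = "recovery"))
  }
  segs$start_min <- cumsum(c(0, segs$duration[-nrow(segs)]))
  segs$end_min <- segs$start_min + segs$duration
  segs
}

#' Bout windows of a protocol
#'
#' Start/end times of each exercise bout (and the rest period) relative to
#' a session start time — the windows steady-state extraction averages
#' over.
#'
#' @param protocol a `lab_protocol`.
#' @param start_time session start (POSIXct, UTC).
#' @return data frame: `label`, `speed`, `start`, `end` (POSIXct).
#' @export
protocol_bout_windows <- function(protocol,
                                  start_time = as.POSIXct("2017-01-01 09:00:00",
                                                          tz = "UTC")) {
  segs <- protocol_timeline(protocol)
  keep <- segs$label != "recovery"
  data.frame(label = segs$label[keep], speed = segs$speed[keep],
             start = start_time + segs$start_min[keep] * 60,
             end = start_time + segs$end_min[keep] * 60)
}

#' Simulate a laboratory treadmill session
#'
#' Generates a 1-s epoch activity-count series and a 1-Hz gas-exchange
#' series for one participant completing a treadmill protocol. Counts per
#' epoch are proportional to speed (`counts_per_kmh`) with multiplicative
#' lognormal noise and are zero at rest/recovery. The steady-state EE
#' target of each segment is the calibration model's prediction at that
#' segment's expected counts/min; oxygen uptake follows a first-order
#' exponential approach to each segment's steady state with time constant
#' `vo2_time_constant`, so measured EE lags instantaneous speed changes the
#' way real on-kinetics do. The respiratory exchange ratio ramps linearly
#' from 0.85 at rest to 1.00 at the fastest bout speed; VCO2 = RER x VO2.
#'
#' @param participant list with at least `id` and `mass_kg`.
#' @param protocol a `lab_protocol`.
#' @param config a `sim_config`.
#' @param start_time session start (POSIXct UTC).
#' @param seed optional seed overriding `config$seed`.
#' @return list: `epochs` (an `epoch_series`, 1-s epochs), `gas`
#'   (a `gas_exchange` series), `bouts` (from [protocol_bout_windows()]).
#' @export
generate_lab_session <- function(participant, protocol = phase1_protocol(),
                                 config = sim_config(),
                                 start_time = as.POSIXct("2017-01-01 09:00:00",
                                                         tz = "UTC"),
                                 seed = NULL) {
  stopifnot(inherits(protocol, "lab_protocol"), inherits(config, "sim_config"))
  if (is.null(participant$mass_kg) || participant$mass_kg <= 0)
    stop_invalid("'participant' needs a positive 'mass_kg'")
  segs <- protocol_timeline(protocol)
  n_sec <- sum(segs$duration) * 60
  if (n_sec != round(n_sec)) stop_invalid("durations must give whole seconds")
  speed_sec <- rep(segs$speed, segs$duration * 60)
  max_speed <- max(protocol$bouts$speed)
  with_seed(seed %||% config$seed, {
    # counts: expected counts/min scaled to the 1-s epoch
    rate_cpm <- speed_sec * config$counts_per_kmh
    counts <- round(rate_cpm / 60 * rlnorm_cv(n_sec, config$counts_noise_cv))
    counts[speed_sec == 0] <- 0
    # steady-state EE target per segment via the generating model
    spd_frac <- if (max_speed > 0) segs$speed / max_speed else segs$speed * 0
    seg_rer <- 0.85 + 0.15 * spd_frac
    seg_ee <- predict_ee(config$model,
                         segs$speed * config$counts_per_kmh,
                         participant$mass_kg)
    seg_ee <- pmax(seg_ee, 0.1)  # physiological floor
    seg_vo2 <- seg_ee / (3.781 + 1.237 * seg_rer)
    vo2_target <- rep(seg_vo2, segs$duration * 60)
    rer_sec <- rep(seg_rer, segs$duration * 60)
    # exact first-order relaxation, 1-s steps
    alpha <- exp(-1 / config$vo2_time_constant)
    vo2 <- numeric(n_sec)
    v <- seg_vo2[1L]
    for (t in seq_len(n_sec)) {
      v <- vo2_target[t] + (v - vo2_target[t]) * alpha
      vo2[t] <- v
    }
    vo2_obs <- vo2 * rlnorm_cv(n_sec, config$vo2_noise_cv)
    gas <- gas_exchange_series(start_time + seq_len(n_sec), vo2_obs,
                               rer_sec * vo2_obs)
    list(epochs = epoch_series(start_time, 1, counts,
                               sprintf("phone-%s", participant$id %||% "x")),
         gas = gas,
         bouts = protocol_bout_windows(protocol, start_time))
  })
}

#' Simulate one 24-h free-living day for a phone/reference device pair
#'
#' Builds a shared minute-level activity structure (a persistent Markov
#' mixture over sedentary-to-vigorous states) at 10-s epochs, then derives
#' two device series from it: the reference wears all day; the phone
#' follows the reference up to a multiplicative scale mismatch and noise.
#' During `nonwear_blocks` both series are zero; during `noncarry_blocks`
#' only the phone is zero (nonwear dominates where blocks overlap).
#' Outside nonwear blocks the reference is kept strictly positive (>= 1
#' count per epoch) so the only long zero runs are the configured ones.
#'
#' @param participant list with `id` and `mass_kg`.
#' @param config a `sim_config` (blocks, phone scale, noise, seed).
#' @param start_time start of the day (POSIXct UTC midnight).
#' @param seed optional seed overriding `config$seed`.
#' @return list of two `epoch_series` (10-s epochs): `phone`, `reference`.
#' @export
generate_freeliving_day <- function(participant, config = sim_config(),
                                    start_time = as.POSIXct("2017-01-02 00:00:00",
                                                            tz = "UTC"),
                                    seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_min <- 1440L
  per_min <- 6L                       # 10-s epochs
  n_ep <- n_min * per_min
  with_seed(seed %||% config$seed, {
    # minute-level activity states: persistent chain, mostly sedentary/light
    states <- c("sedentary", "light", "moderate", "hard", "veryhard")
    mean_cpm <- c(sedentary = 40, light = 600, moderate = 1262,
                  hard = 3500, veryhard = 8500)
    P <- rbind(sedentary = c(0.92, 0.06, 0.010, 0.008, 0.002),
               light     = c(0.10, 0.85, 0.030, 0.015, 0.005),
               moderate  = c(0.05, 0.10, 0.800, 0.040, 0.010),
               hard      = c(0.03, 0.05, 0.050, 0.850, 0.020),
               veryhard  = c(0.03, 0.05, 0.020, 0.100, 0.800))
    st <- integer(n_min); st[1L] <- 1L
    for (i in 2:n_min) st[i] <- sample.int(5L, 1L, prob = P[st[i - 1L], ])
    cpm <- mean_cpm[st] * rlnorm_cv(n_min, 0.3)
    ref <- pmax(1, round(rep(cpm / per_min, each = per_min) *
                           rlnorm_cv(n_ep, config$counts_noise_cv)))
    phone <- pmax(1, round(ref * config$phone_scale *
                             rlnorm_cv(n_ep, config$counts_noise_cv)))
    block_epochs <- function(blocks) {
      idx <- integer(0)
      for (b in blocks) {
        s <- floor(b[1L] * per_min) + 1L
        e <- floor((b[1L] + b[2L]) * per_min)
        idx <- c(idx, s:e)
      }
      idx
    }
    nw <- block_epochs(config$nonwear_blocks)
    nc <- block_epochs(config$noncarry_blocks)
    ref[nw] <- 0
    phone[unique(c(nw, nc))] <- 0
    list(phone = epoch_series(start_time, 10, phone,
                              sprintf("phone-%s", participant$id %||% "x")),
         reference = epoch_series(start_time, 10, ref,
                                  sprintf("actigraph-%s",
                                          participant$id %||% "x")))
  })
}

#' Simulate a GPS fix log along a waypoint path
#'
#' Interpolates a track through `waypoints` using the power-aware sampling
#' rule of phone GPS loggers: one fix per minute while moving, one per 30
#' minutes while stationary (segment speed <= `move_threshold`). Each fix
#' is assigned an accuracy radius (drawn from the configured bin mixture,
#' with a `gps_outlier_fraction` chance of a gross > 100 m outlier) and its
#' position is perturbed by isotropic Gaussian noise with SD =
#' `accuracy_radius / 2` (times `gps_noise_scale`), so outliers also carry
#' large displacements.
#'
#' @param waypoints data frame with columns `lat`, `lon`, `time` (POSIXct,
#'   strictly increasing).
#' @param config a `sim_config`.
#' @param move_threshold m/s separating stationary from moving segments.
#' @param seed optional seed overriding `config$seed`.
#' @return data frame of fixes: `time`, `lat`, `lon`, `accuracy` (m).
#' @export
generate_gps_track <- function(waypoints, config = sim_config(),
                               move_threshold = 0.5, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("lat", "lon", "time") %in% names(waypoints)))
    stop_invalid("'waypoints' needs columns lat, lon, time")
  wt <- as.numeric(as.POSIXct(waypoints$time, tz = "UTC"))
  if (nrow(waypoints) < 2L || any(diff(wt) <= 0))
    stop_invalid("waypoint times must be strictly increasing (>= 2 points)")
  lat0 <- mean(waypoints$lat) * pi / 180
  mdeg <- 6371000 * pi / 180          # metres per degree latitude
  with_seed(seed %||% config$seed, {
    times <- wt[1L]
    for (i in seq_len(nrow(waypoints) - 1L)) {
      dx <- (waypoints$lon[i + 1L] - waypoints$lon[i]) * mdeg * cos(lat0)
      dy <- (waypoints$lat[i + 1L] - waypoints$lat[i]) * mdeg
      v <- sqrt(dx^2 + dy^2) / (wt[i + 1L] - wt[i])
      spacing <- if (v > move_threshold) 60 else 1800
      seg <- seq(wt[i], wt[i + 1L], by = spacing)
      if (seg[length(seg)] < wt[i + 1L] && i == nrow(waypoints) - 1L)
        seg <- c(seg, wt[i + 1L])
      times <- c(times, seg[-1L])
    }
    lat <- stats::approx(wt, waypoints$lat, xout = times)$y
    lon <- stats::approx(wt, waypoints$lon, xout = times)$y
    n <- length(times)
    outlier <- stats::runif(n) < config$gps_outlier_fraction
    acc <- numeric(n)
    ngood <- sum(!outlier)
    if (ngood) {
      bin <- sample.int(4L, ngood, replace = TRUE,
                        prob = config$gps_bin_probs / sum(config$gps_bin_probs))
      lo <- c(5, 26, 51, 76)[bin]; hi <- c(25, 50, 75, 100)[bin]
      acc[!outlier] <- stats::runif(ngood, lo, hi)
    }
    if (any(outlier))
      acc[outlier] <- pmax(101, stats::rlnorm(sum(outlier),
                                              meanlog = log(2370), sdlog = 0.9))
    if (config$gps_noise_scale > 0) {
      sdm <- acc / 2 * config$gps_noise_scale
      lat <- lat + stats::rnorm(n, 0, sdm) / mdeg
      lon <- lon + stats::rnorm(n, 0, sdm) / (mdeg * cos(lat0))
    }
    data.frame(time = as.POSIXct(times, tz = "UTC",
                                 origin = "1970-01-01"),
               lat = lat, lon = lon, accuracy = acc)
  })
}
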