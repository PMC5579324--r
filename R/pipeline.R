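# window mean counts/min of a 1-s epoch series over (end - w, end]
window_counts_per_min <- function(series, window_start, window_end, w = 2) {
  t <- as.numeric(epoch_times(series))
  e <- as.numeric(as.POSIXct(window_end, tz = "UTC"))
  sel <- t > e - w * 60 & t <= e
  if (!any(sel)) stop_invalid("empty count window")
  sum(series$counts[sel]) / w
}

#' Run the laboratory validation end-to-end on a synthetic cohort
#'
#' Simulates a treadmill cohort (phone counts, reference accelerometer
#' counts, and criterion gas exchange per participant), extracts
#' steady-state means over the trailing 2 min of rest and of each bout,
#' fits the count-to-EE calibration on the pooled (counts, mass, criterion
#' EE) rows, predicts EE for both devices, and runs the full agreement
#' battery: criterion (phone vs calorimetry) and convergent (phone vs
#' reference device), each overall, by intensity level, and per
#' individual, plus the time-synchronized minute-by-minute group pattern.
#'
#' @param n_participants cohort size (>= 2); default 21.
#' @param protocol a `lab_protocol`; default [phase1_protocol()].
#' @param config a `sim_config`.
#' @param device_offset_kcal constant EE offset injected into the phone
#'   device (kcal/min), emulating a systematic convergent bias scenario.
#' @param averaging_window steady-state window, minutes.
#' @param seed master seed; per-participant streams are derived from it.
#' @return list of class `phase1_lab`: `model` (fitted `ee_calibration`),
#'   `steady_state` (per participant x window table), `criterion` and
#'   `convergent` `agreement_report`s, `pattern` (time-synchronized group
#'   means).
#' @export
run_phase1_lab <- function(n_participants = 21, protocol = phase1_protocol(),
                           config = sim_config(), device_offset_kcal = 0,
                           averaging_window = 2, seed = 1L) {
  if (n_participants < 2L) stop_invalid("need at least 2 participants")
  rows <- list(); pattern_rows <- list()
  masses <- with_seed(seed, {
    m <- stats::rnorm(n_participants, 70.5, 11.6)
    pmax(m, 45)
  })
  for (i in seq_len(n_participants)) {
    p <- list(id = i, mass_kg = masses[i])
    s_phone <- generate_lab_session(p, protocol, config,
                                    seed = seed + 13L * i)
    s_ref <- generate_lab_session(p, protocol, config,
                                  seed = seed + 13L * i + 7L)
    bw <- s_phone$bouts
    for (j in seq_len(nrow(bw))) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, label = bw$label[j], speed = bw$speed[j],
        mass_kg = p$mass_kg,
        counts_per_min = window_counts_per_min(s_phone$epochs, bw$start[j],
                                               bw$end[j], averaging_window),
        ref_counts_per_min = window_counts_per_min(s_ref$epochs, bw$start[j],
                                                   bw$end[j], averaging_window),
        ee_kcal_min = bout_steady_state_mean(s_phone$gas, bw$start[j],
                                             bw$end[j], averaging_window))
    }
    # per-minute series for the time-synchronized pattern
    cpm <- resample_to_counts_per_min(s_phone$epochs)
    n_min <- length(cpm$counts)
    gas_min <- vapply(seq_len(n_min), function(m) {
      window_mean(s_phone$gas, cpm$start_time + m * 60, 1)
    }, numeric(1))
    pattern_rows[[length(pattern_rows) + 1L]] <- data.frame(
      participant = i, minute = rep(seq_len(n_min), 2L),
      method = rep(c("phone_counts_ee", "calorimetry_ee"), each = n_min),
      value = c(rep(NA_real_, n_min), gas_min),
      cpm = c(cpm$counts, rep(NA_real_, n_min)))
  }
  ss <- do.call(rbind, rows)
  model <- fit_calibration(ss[, c("counts_per_min", "mass_kg", "ee_kcal_min")])
  ss$phone_ee <- predict_ee(model, ss$counts_per_min, ss$mass_kg) +
    device_offset_kcal
  ss$ref_ee <- predict_ee(model, ss$ref_counts_per_min, ss$mass_kg)
  criterion <- agreement_report(ss$phone_ee, ss$ee_kcal_min,
                                level = ss$label, participant = ss$participant)
  convergent <- agreement_report(ss$phone_ee, ss$ref_ee,
                                 level = ss$label, participant = ss$participant)
  pat <- do.call(rbind, pattern_rows)
  phone_rows <- pat$method == "phone_counts_ee"
  pat$value[phone_rows] <- predict_ee(model, pat$cpm[phone_rows],
                                      masses[pat$participant[phone_rows]]) +
    device_offset_kcal
  pattern <- time_synchronized_group_pattern(
    pat[, c("participant", "minute", "method", "value")])
  structure(list(model = model, steady_state = ss, criterion = criterion,
                 convergent = convergent, pattern = pattern,
                 protocol = protocol),
            class = "phase1_lab")
}

#' @export
print.phase1_lab <- function(x, ...) {
  cat("Laboratory validation run (synthetic cohort)\n\n")
  print(x$model)
  cat("\n-- Criterion agreement (device vs calorimetry) --\n")
  print(x$criterion)
  cat("\n-- Convergent agreement (device vs reference accelerometer) --\n")
  print(x$convergent)
  invisible(x)
}

#' Run the free-living validation end-to-end on a synthetic cohort
#'
#' Simulates 24-h phone/reference day pairs, cleans them (minute
#' resampling, nonwear removal on native epochs, valid-day screen), and
#' runs the convergent agreement battery on minute-level paired EE,
#' stratified by intensity level classified from the reference device.
#' Participants whose configured nonwear leaves under `min_wear` wear
#' minutes are excluded and logged — never silently dropped.
#'
#' @param n_participants cohort size; default 10.
#' @param fail_indices participants constructed to fail the wear-time
#'   screen (given nonwear blocks exceeding the day's slack).
#' @param config base `sim_config`; per-participant block layouts are
#'   derived from it.
#' @param model `ee_calibration` used for count-based EE on both devices.
#' @param thresholds `intensity_thresholds` for level stratification.
#' @param min_wear valid-day threshold, minutes.
#' @param seed master seed.
#' @return list of class `phase1_freeliving`: `report` (convergent
#'   `agreement_report` by level), `daily` (per-participant summaries),
#'   `exclusions` (data frame of participant, wear minutes, reason),
#'   `included` ids.
#' @export
run_phase1_freeliving <- function(n_participants = 10, fail_indices = c(1L, 2L),
                                  config = sim_config(),
                                  model = published_calibration(),
                                  thresholds = published_thresholds(),
                                  min_wear = 600, seed = 1L) {
  minute_rows <- list(); daily <- list()
  exclusions <- data.frame(participant = integer(), wear_minutes = numeric(),
                           reason = character())
  for (i in seq_len(n_participants)) {
    cfg <- config
    if (i %in% fail_indices) {
      # two long device-off blocks leave < 10 h of wear
      cfg$nonwear_blocks <- list(c(0, 500), c(560, 400))
    } else if (!length(cfg$nonwear_blocks)) {
      cfg$nonwear_blocks <- list(c(30, 90))
      cfg$noncarry_blocks <- list(c(800, 30))
    }
    day <- generate_freeliving_day(list(id = i, mass_kg = 70.5), cfg,
                                   seed = seed + 101L * i)
    mask <- detect_nonwear(day$reference)
    valid <- is_valid_day(day$reference, mask, min_wear)
    if (!valid) {
      exclusions <- rbind(exclusions, data.frame(
        participant = i, wear_minutes = attr(valid, "wear_minutes"),
        reason = sprintf("wear time below %d min", min_wear)))
      next
    }
    per_min <- 60 / day$reference$epoch_duration
    ref_cpm <- resample_to_counts_per_min(day$reference)
    phone_cpm <- resample_to_counts_per_min(day$phone)
    n_min <- length(ref_cpm$counts)
    wear_mat <- matrix(mask$wear[seq_len(n_min * per_min)], nrow = per_min)
    minute_wear <- apply(wear_mat, 2L, all)
    sel <- which(minute_wear)
    minute_rows[[length(minute_rows) + 1L]] <- data.frame(
      participant = i, minute = sel,
      phone_ee = predict_ee(model, phone_cpm$counts[sel], 70.5),
      ref_ee = predict_ee(model, ref_cpm$counts[sel], 70.5),
      level = classify_intensity(ref_cpm$counts[sel], thresholds))
    daily[[length(daily) + 1L]] <- summarize_day(
      day$reference, mask, thresholds, model, 70.5, min_wear = min_wear)
  }
  if (!length(minute_rows))
    stop_invalid("empty cohort: no participant passed the valid-day screen")
  md <- do.call(rbind, minute_rows)
  report <- agreement_report(md$phone_ee, md$ref_ee, level = md$level,
                             participant = md$participant)
  structure(list(report = report, minutes = md, daily = daily,
                 exclusions = exclusions,
                 included = unique(md$participant)),
            class = "phase1_freeliving")
}

#' @export
print.phase1_freeliving <- function(x, ...) {
  cat(sprintf("Free-living validation run: %d participant(s) analysed, %d excluded\n\n",
              length(x$included), nrow(x$exclusions)))
  if (nrow(x$exclusions)) print(x$exclusions, row.names = FALSE)
  print(x$report)
  invisible(x)
}

#' Cross-validate a calibration model on a synthetic walking sample
#'
#' Emulates an independent cross-validation sample on different hardware:
#' walking bouts only (4/5/6 km/h), counts generated from the same linear
#' counts-vs-speed world, and measured EE equal to the generating model's
#' prediction plus Gaussian noise of SD `noise_sd`. The supplied model is
#' applied, never refitted.
#'
#' @param model the fitted/published `ee_calibration` to validate.
#' @param n_participants independent sample size; default 42.
#' @param speeds walking bout speeds, km/h.
#' @param noise_sd measurement noise SD, kcal/min; default 1.10.
#' @param config `sim_config` (counts scale/noise, generating model).
#' @param seed integer seed.
#' @return list: `see`, `r_squared`, `n`, plus the observation table in
#'   `obs`.
#' @export
run_phase2_crossval <- function(model, n_participants = 42,
                                speeds = c(4, 5, 6), noise_sd = 1.10,
                                config = sim_config(), seed = 1L) {
  if (missing(model) || !inherits(model, "ee_calibration"))
    stop_invalid("a fitted 'ee_calibration' model must be supplied")
  obs <- with_seed(seed, {
    mass <- pmax(stats::rnorm(n_participants, 68, 12), 45)
    g <- expand.grid(participant = seq_len(n_participants), speed = speeds)
    g$mass_kg <- mass[g$participant]
    g$counts_per_min <- g$speed * config$counts_per_kmh *
      rlnorm_cv(nrow(g), config$counts_noise_cv)
    g$ee_kcal_min <- predict_ee(config$model, g$counts_per_min, g$mass_kg) +
      stats::rnorm(nrow(g), 0, noise_sd)
    g
  })
  cv <- cross_validate(model, obs)
  c(cv, list(obs = obs))
}
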