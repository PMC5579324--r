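# shared fixture builders (all generated in code; no data files)

t0 <- function() as.POSIXct("2017-01-01 09:00:00", tz = "UTC")

# gas-exchange series with given per-second vo2/vco2 vectors (1 Hz)
make_gas <- function(vo2, vco2 = 0.8 * vo2, start = t0()) {
  gas_exchange_series(start + seq_along(vo2), vo2, vco2)
}

# epoch series from per-minute zero/nonzero pattern, at 60-s epochs
minutes_series <- function(counts, start = t0()) {
  epoch_series(start, 60, counts)
}

# a day series (10-s epochs) with given zero-run layout:
# active everywhere except `zero_blocks`, list of c(start_min, duration_min)
day_series <- function(zero_blocks = list(), base = 50L) {
  n <- 1440L * 6L
  counts <- rep(base, n)
  for (b in zero_blocks) {
    idx <- (b[1L] * 6L + 1L):((b[1L] + b[2L]) * 6L)
    counts[idx] <- 0L
  }
  epoch_series(as.POSIXct("2017-01-02 00:00:00", tz = "UTC"), 10, counts)
}

# straight walking track: n fixes, `spacing_m` apart, `dt_s` seconds apart
walking_fixes <- function(n = 20, spacing_m = 100, dt_s = 60,
                          lat0 = 53, lon0 = -6.25) {
  mdeg <- 6371000 * pi / 180
  data.frame(time = t0() + (seq_len(n) - 1) * dt_s,
             lat = lat0 + (seq_len(n) - 1) * spacing_m / mdeg,
             lon = lon0, accuracy = 10)
}
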