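# Fixture builders: a full station-day (or series) of records constructed
# in code, with per-channel overrides.

day_grid <- function(date = "2017-03-01", cadence = 10, tz = "UTC") {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = tz)
  start + seq(0, by = cadence * 60, length.out = 1440 / cadence)
}

make_day_records <- function(date = "2017-03-01", cadence = 10,
                             air_temp = 10, rel_humidity = 0.5,
                             wind_speed = 2, precip = 0,
                             soil_vwc_10cm = 0.15, soil_vwc_40cm = 0.15,
                             station_id = 1, tz = "UTC") {
  ts <- day_grid(date, cadence, tz)
  n <- length(ts)
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  data.frame(timestamp = ts, station_id = station_id,
             air_temp = rep_n(air_temp), rel_humidity = rep_n(rel_humidity),
             wind_speed = rep_n(wind_speed), precip = rep_n(precip),
             soil_vwc_10cm = rep_n(soil_vwc_10cm),
             soil_vwc_40cm = rep_n(soil_vwc_40cm))
}

# a bare daily summary row for driving update_runs()/assess_series()
make_summary <- function(date, t_max = 10, rh_min = 0.5, precip_total = 0,
                         wind_max = 2, humus_vwc = 0.15, soil40_vwc = 0.15,
                         dry_run = NA_integer_, wet_run = NA_integer_,
                         n_records = 144L, gap_flag = FALSE,
                         station_id = 1) {
  s <- data.frame(date = as.Date(date), station_id = station_id,
                  t_max = t_max, rh_min = rh_min,
                  precip_total = precip_total, wind_max = wind_max,
                  humus_vwc = humus_vwc, soil40_vwc = soil40_vwc,
                  dry_run = as.integer(dry_run), wet_run = as.integer(wet_run),
                  n_records = n_records, gap_flag = gap_flag)
  class(s) <- c("daily_summary", "data.frame")
  s
}

run_summaries <- function(precips, start = "2017-04-01", ...) {
  cfg <- aggregation_config()
  prev <- NULL
  out <- vector("list", length(precips))
  for (i in seq_along(precips)) {
    s <- make_summary(as.Date(start) + i - 1L, precip_total = precips[i], ...)
    s <- update_runs(prev, s, cfg)
    prev <- s
    out[[i]] <- s
  }
  res <- do.call(rbind, out)
  class(res) <- c("daily_summary", "data.frame")
  res
}
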