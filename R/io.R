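# CSV interchange. The canonical sensor file dialect is
#   timestamp,station_id,air_temp_c,rh_pct,wind_ms,precip_mm,vwc10_pct,vwc40_pct
# with percent columns converted to fractions on read and back to percent
# on write, so files match what station dataloggers export while the
# package works in fractions internally.

SENSOR_CSV_HEADER <- c("timestamp", "station_id", "air_temp_c", "rh_pct",
                       "wind_ms", "precip_mm", "vwc10_pct", "vwc40_pct")

#' Read a sensor record CSV
#'
#' @param path CSV file with header `timestamp,station_id,air_temp_c,
#'   rh_pct,wind_ms,precip_mm,vwc10_pct,vwc40_pct`. Timestamps are parsed
#'   as `"%Y-%m-%d %H:%M:%S"` in `tz`.
#' @param tz time zone of the timestamps (default `"UTC"`).
#' @return data.frame of sensor records in internal units (fractions for
#'   humidity and soil moisture).
#' @export
read_sensor_csv <- function(path, tz = "UTC") {
  if (!file.exists(path)) {
    fg_stop(sprintf("input file not found: %s", path), "firegrade_file_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SENSOR_CSV_HEADER, names(raw))
  if (length(missing)) {
    fg_stop(sprintf("sensor CSV %s lacks column(s): %s", path,
                    paste(missing, collapse = ", ")),
            "firegrade_parse_error")
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = tz)
  if (anyNA(ts)) {
    fg_stop(sprintf("unparseable timestamp at line %d of %s",
                    which(is.na(ts))[1] + 1L, path),
            "firegrade_parse_error")
  }
  data.frame(timestamp = ts, station_id = raw$station_id,
             air_temp = raw$air_temp_c, rel_humidity = raw$rh_pct / 100,
             wind_speed = raw$wind_ms, precip = raw$precip_mm,
             soil_vwc_10cm = raw$vwc10_pct / 100,
             soil_vwc_40cm = raw$vwc40_pct / 100)
}

#' Write sensor records to the canonical CSV dialect
#'
#' @param records internal sensor record data.frame (see
#'   [read_sensor_csv()] for the inverse).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(records, path) {
  out <- data.frame(
    timestamp = format(records$timestamp, "%Y-%m-%d %H:%M:%S"),
    station_id = records$station_id,
    air_temp_c = round(records$air_temp, 2),
    rh_pct = round(records$rel_humidity * 100, 2),
    wind_ms = round(records$wind_speed, 2),
    precip_mm = round(records$precip, 3),
    vwc10_pct = round(records$soil_vwc_10cm * 100, 2),
    vwc40_pct = round(records$soil_vwc_40cm * 100, 2))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read daily summaries and assessments
#'
#' Plain CSV writers/readers for the pipeline's intermediate tables, with
#' stable column order so re-running on identical input is byte-identical.
#'
#' @param x data.frame from [aggregate_daily()] or [assess_series()].
#' @param path file path.
#' @return `path` (writers, invisibly) or a data.frame (readers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_daily_csv <- function(x, path) {
  out <- x
  out$date <- format(out$date)
  num <- vapply(out, is.numeric, TRUE) & names(out) != "station_id"
  out[num] <- lapply(out[num], function(v) round(v, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_daily_summary_csv <- function(path) {
  if (!file.exists(path)) {
    fg_stop(sprintf("input file not found: %s", path), "firegrade_file_error")
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  class(x) <- c("daily_summary", "data.frame")
  x
}
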