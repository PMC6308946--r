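# Daily aggregation: fixed-cadence sensor records -> the daily inputs the
# index equations consume (Tmax, RHmin, precip total, wind max, humus VWC)
# plus the consecutive dry/wet day run counters.

CONTINUOUS_CHANNELS <- c("air_temp", "rel_humidity", "wind_speed",
                         "soil_vwc_10cm", "soil_vwc_40cm")
RECORD_COLUMNS <- c("timestamp", "station_id", "air_temp", "rel_humidity",
                    "wind_speed", "precip", "soil_vwc_10cm", "soil_vwc_40cm")

#' Aggregation configuration
#'
#' @param cadence sampling interval in minutes (default 10, the station
#'   logging interval).
#' @param rain_day_threshold daily precipitation (mm) at or above which a
#'   day counts as a rain day (default 0.1).
#' @param max_gap longest data gap (minutes) bridged by interpolation
#'   (default 30; longer gaps flag the day).
#' @param min_coverage minimum fraction of expected records per day
#'   (default 0.8); below it [summarize_day()] raises a low-coverage error
#'   carrying the partial summary.
#' @param tz time zone in which days are delimited (station-local
#'   midnight; default `"UTC"`).
#' @return object of class `aggregation_config`.
#' @export
aggregation_config <- function(cadence = 10, rain_day_threshold = 0.1,
                               max_gap = 30, min_coverage = 0.8,
                               tz = "UTC") {
  fg_validate(cadence > 0 && rain_day_threshold > 0 && max_gap > 0,
              "cadence, rain_day_threshold and max_gap must be positive")
  fg_validate(min_coverage > 0 && min_coverage <= 1,
              "min_coverage must be in (0, 1]")
  fg_validate(1440 %% cadence == 0,
              "`cadence` must divide 1440 minutes")
  structure(list(cadence = cadence, rain_day_threshold = rain_day_threshold,
                 max_gap = max_gap, min_coverage = min_coverage, tz = tz),
            class = "aggregation_config")
}

# drop duplicated timestamps (keep first) and sort; idempotent ingestion
normalize_records <- function(records) {
  records <- records[order(records$timestamp), , drop = FALSE]
  records[!duplicated(records$timestamp), , drop = FALSE]
}

empty_summary <- function(date, station_id) {
  data.frame(date = date, station_id = station_id,
             t_max = NA_real_, rh_min = NA_real_, precip_total = NA_real_,
             wind_max = NA_real_, humus_vwc = NA_real_,
             soil40_vwc = NA_real_,
             dry_run = NA_integer_, wet_run = NA_integer_,
             n_records = 0L, gap_flag = TRUE)
}

#' Summarise one station-day of sensor records
#'
#' Computes the daily index inputs from the records of a single station on
#' a single calendar day: maximum air temperature, minimum relative
#' humidity, precipitation total, maximum wind speed, and the mean 10 cm
#' (humus-layer) and 40 cm volumetric water contents. Records are
#' de-duplicated on timestamp and re-sorted, so aggregation is invariant
#' to row order. Gaps up to `config$max_gap` minutes are bridged by linear
#' interpolation of the continuous channels (precipitation gaps are
#' bridged as zeros); longer gaps leave the missing stretch out of the
#' statistics and set `gap_flag`.
#'
#' @param records data.frame with columns `timestamp` (POSIXct),
#'   `station_id`, `air_temp`, `rel_humidity`, `wind_speed`, `precip`,
#'   `soil_vwc_10cm`, `soil_vwc_40cm` — one station, one day.
#' @param config an [aggregation_config()].
#' @return one-row data.frame (class `daily_summary`) with the run
#'   counters `dry_run`/`wet_run` unset (NA); see [update_runs()].
#' @section Errors:
#' Empty input raises `firegrade_empty_day_error`; coverage below
#' `config$min_coverage` raises `firegrade_low_coverage_error` whose
#' condition carries the partial summary in `$summary`.
#' @export
summarize_day <- function(records, config = aggregation_config()) {
  if (is.null(records) || nrow(records) == 0L) {
    fg_stop("no records for this day", "firegrade_empty_day_error")
  }
  fg_validate(all(RECORD_COLUMNS %in% names(records)),
              paste("records must have columns:",
                    paste(RECORD_COLUMNS, collapse = ", ")))
  fg_validate(length(unique(records$station_id)) == 1L,
              "records must come from a single station")
  records <- normalize_records(records)
  days <- unique(as.Date(records$timestamp, tz = config$tz))
  fg_validate(length(days) == 1L,
              "records must belong to a single calendar day")

  per_day <- as.integer(1440 / config$cadence)
  day_start <- as.POSIXct(paste(days, "00:00:00"), tz = config$tz)
  grid <- day_start + seq(0L, by = config$cadence * 60, length.out = per_day)
  # snap observed timestamps onto the grid (floor to cadence)
  snap <- day_start + floor(as.numeric(records$timestamp - day_start,
                                       units = "mins") / config$cadence) *
    config$cadence * 60
  idx <- match(as.numeric(grid), as.numeric(snap))

  gmax_steps <- floor(config$max_gap / config$cadence)
  filled <- list()
  long_gap <- FALSE
  for (ch in c(CONTINUOUS_CHANNELS, "precip")) {
    v <- records[[ch]][idx]
    if (anyNA(v)) {
      runs <- rle(is.na(v))
      if (any(runs$values & runs$lengths > gmax_steps)) long_gap <- TRUE
      if (ch == "precip") {
        # short missing stretches are treated as rain-free
        short <- rep(runs$values & runs$lengths <= gmax_steps, runs$lengths)
        v[short] <- 0
      } else {
        v <- zoo::na.approx(v, na.rm = FALSE, maxgap = gmax_steps)
        # leading/trailing short gaps: carry the nearest observation
        still <- rep(rle(is.na(v))$values & rle(is.na(v))$lengths <= gmax_steps,
                     rle(is.na(v))$lengths)
        if (any(still)) {
          v2 <- zoo::na.locf(zoo::na.locf(v, na.rm = FALSE),
                             fromLast = TRUE, na.rm = FALSE)
          v[still] <- v2[still]
        }
      }
    }
    filled[[ch]] <- v
  }

  n_obs <- sum(!is.na(idx))
  out <- data.frame(
    date = days, station_id = records$station_id[1],
    t_max = max(filled$air_temp, na.rm = TRUE),
    rh_min = min(filled$rel_humidity, na.rm = TRUE),
    precip_total = sum(filled$precip, na.rm = TRUE),
    wind_max = max(filled$wind_speed, na.rm = TRUE),
    humus_vwc = mean(filled$soil_vwc_10cm, na.rm = TRUE),
    soil40_vwc = mean(filled$soil_vwc_40cm, na.rm = TRUE),
    dry_run = NA_integer_, wet_run = NA_integer_,
    n_records = n_obs, gap_flag = long_gap)
  class(out) <- c("daily_summary", "data.frame")

  if (n_obs / per_day < config$min_coverage) {
    out$gap_flag <- TRUE
    stop(errorCondition(
      sprintf("day %s has coverage %.2f below min_coverage %.2f",
              format(days), n_obs / per_day, config$min_coverage),
      summary = out,
      class = c("firegrade_low_coverage_error", "firegrade_error", "error")))
  }
  out
}

#' Advance the dry/wet day run counters
#'
#' A day with `precip_total` below `config$rain_day_threshold` extends the
#' dry run and zeroes the wet run, and vice versa. Exactly one of the two
#' counters is positive on every scored day.
#'
#' @param previous the previous day's completed `daily_summary`, or `NULL`
#'   at the start of a series (or after a wholly missing day, which resets
#'   both counters).
#' @param today a `daily_summary` with counters unset.
#' @param config an [aggregation_config()].
#' @return `today` with `dry_run` and `wet_run` set.
#' @export
#' @examples
#' cfg <- aggregation_config()
#' # first day, no rain: dry_run starts at 1
update_runs <- function(previous, today, config = aggregation_config()) {
  if (!is.null(previous)) {
    fg_validate(!is.na(previous$dry_run) && !is.na(previous$wet_run),
                "previous day's run counters are unset")
    if (as.integer(today$date - previous$date) != 1L) {
      fg_stop(sprintf("day %s does not immediately follow %s",
                      format(today$date), format(previous$date)),
              "firegrade_sequence_error")
    }
  }
  rainy <- !is.na(today$precip_total) &&
    today$precip_total >= config$rain_day_threshold
  if (rainy) {
    today$wet_run <- if (is.null(previous)) 1L else previous$wet_run + 1L
    today$dry_run <- 0L
  } else {
    today$dry_run <- if (is.null(previous)) 1L else previous$dry_run + 1L
    today$wet_run <- 0L
  }
  today
}

#' Aggregate a multi-day record series into daily summaries
#'
#' Splits the records of one station into station-local calendar days,
#' summarises each day and threads the dry/wet run counters through the
#' series. Low-coverage days are kept with `gap_flag = TRUE`; wholly
#' missing days reset the run counters (conservative) and are reported as
#' flagged rows with no data.
#'
#' @param records sensor record data.frame spanning one or more days
#'   (single station).
#' @param config an [aggregation_config()].
#' @return data.frame of daily summaries, one row per calendar day from
#'   the first to the last observed day.
#' @export
aggregate_daily <- function(records, config = aggregation_config()) {
  fg_validate(nrow(records) > 0L, "no records to aggregate")
  records <- normalize_records(records)
  day <- as.Date(records$timestamp, tz = config$tz)
  all_days <- seq(min(day), max(day), by = "day")
  prev <- NULL
  rows <- vector("list", length(all_days))
  for (i in seq_along(all_days)) {
    d <- all_days[i]
    sub <- records[day == d, , drop = FALSE]
    if (nrow(sub) == 0L) {
      rows[[i]] <- empty_summary(d, records$station_id[1])
      prev <- NULL  # a wholly missing day breaks the run counters
      next
    }
    s <- tryCatch(summarize_day(sub, config),
                  firegrade_low_coverage_error = function(e) e$summary)
    s <- update_runs(prev, s, config)
    prev <- s
    rows[[i]] <- s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("daily_summary", "data.frame")
  out
}

#' Score a series of daily summaries
#'
#' Substitutes each day's aggregates into the component index curves, adds
#' the phenology calendar value and the humus-moisture correction, and
#' classifies the composite index onto the five-grade scale. Days with
#' `gap_flag` are still scored but carry the flag as a quality marker;
#' days with no data at all are skipped.
#'
#' @param summaries data.frame from [aggregate_daily()] (run counters set).
#' @param phenology a [phenology_config()].
#' @param params index-curve coefficients: the published reference set
#'   ([reference_parameters()], default) or refitted coefficients in the
#'   same shape (e.g. built from [refit_builtin()]).
#' @param c_run_counter which run counter feeds the precipitation index's
#'   `t`: `"dry"` (default) uses the consecutive rain-free day count,
#'   `"wet"` the consecutive rain-day count.
#' @return data.frame (class `fire_assessment`) with one row per scored
#'   day: `date`, `station_id`, the six component scores, `total`,
#'   `grade`, `gap_flag`.
#' @export
assess_series <- function(summaries, phenology = phenology_config(),
                          params = reference_parameters(),
                          c_run_counter = c("dry", "wet")) {
  c_run_counter <- match.arg(c_run_counter)
  scored <- summaries[summaries$n_records > 0L, , drop = FALSE]
  fg_validate(nrow(scored) > 0L, "no scorable days")
  if (anyNA(scored$dry_run) || anyNA(scored$wet_run)) {
    fg_stop("run counters are unset; call update_runs()/aggregate_daily() first",
            "firegrade_state_error")
  }
  t_run <- if (c_run_counter == "dry") scored$dry_run else scored$wet_run
  y_a <- index_a(scored$t_max, params$A)
  y_b <- index_b(scored$rh_min, params$B)
  y_c <- index_c(scored$precip_total, t_run, params$C)
  y_d <- index_d(scored$wind_max, params$D)
  y_e1 <- index_e1(scored$date, phenology)
  y_e2 <- index_e2(scored$humus_vwc)
  cg <- composite_and_grade(y_a, y_b, y_c, y_d, y_e1, y_e2)
  out <- data.frame(date = scored$date, station_id = scored$station_id,
                    y_a = y_a, y_b = y_b, y_c = y_c, y_d = y_d,
                    y_e1 = y_e1, y_e2 = y_e2,
                    total = cg$total, grade = cg$grade,
                    gap_flag = scored$gap_flag)
  rownames(out) <- NULL
  class(out) <- c("fire_assessment", "data.frame")
  out
}
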