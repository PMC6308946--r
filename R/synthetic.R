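# Synthetic station weather. The generator emulates the qualitative
# behaviour of a mid-latitude forest station in the spring fire season:
# a diurnal temperature cycle with autocorrelated noise and slow synoptic
# drift, humidity anti-correlated with temperature, wind sampled from a
# Weibull distribution, rain occurrence as a daily two-state Markov chain
# with the day's amount spread over a contiguous event window, and a
# two-layer soil bucket in which the 10 cm layer rises quickly with rain
# and relaxes slowly back toward a dry floor while the 40 cm layer tracks
# the 10 cm layer with a much smaller coupling.

# All randomness flows from one seed through named substreams so the
# weather and the telemetry channel can be varied independently.
substream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Weather generator configuration
#'
#' Defaults describe a northern-China spring fire season (the regime the
#' grading method targets): mean air temperature 12 degC with a 6 degC
#' diurnal amplitude, humidity around 55\% anti-correlated with
#' temperature, a Weibull wind with scale 3 m/s, rain on roughly one day
#' in five with 5 mm on a wet day, and a soil bucket whose 10 cm layer
#' gains 0.01 VWC per mm of rain and loses 5\% of its excess over the dry
#' floor per day.
#'
#' @param seed integer master seed.
#' @param days number of simulated days (default 92, one spring campaign).
#' @param cadence sampling interval in minutes (default 10).
#' @param start_date first simulated day (default `"2017-03-01"`).
#' @param station_id numeric station identifier (default 1).
#' @param temp_mean,temp_diurnal_amp,temp_noise_sd temperature regime in
#'   degC; noise is AR(1) within the day plus an AR(1) day-to-day
#'   synoptic offset.
#' @param rh_base mean relative humidity (fraction).
#' @param rh_temp_coupling humidity drop per degC above `temp_mean`.
#' @param rh_noise_sd humidity noise standard deviation (fraction).
#' @param wind_scale,wind_shape Weibull parameters of the 10-min wind.
#' @param p_wet_given_wet,p_wet_given_dry daily rain-occurrence Markov
#'   chain transition probabilities.
#' @param rain_event_mean_mm mean rain amount on a wet day (exponential).
#' @param soil_infiltration_gain VWC gained per mm of rain in an interval.
#' @param soil10_decay_per_day fraction of the 10 cm layer's excess over
#'   `soil_floor` lost per day.
#' @param soil40_coupling fraction per day by which the 40 cm layer
#'   relaxes toward the 10 cm layer.
#' @param soil_floor,soil_cap bounds of the soil moisture state (VWC).
#' @return object of class `weather_gen_config`.
#' @export
weather_gen_config <- function(seed = 1L, days = 92L, cadence = 10,
                               start_date = "2017-03-01", station_id = 1,
                               temp_mean = 12, temp_diurnal_amp = 6,
                               temp_noise_sd = 1.5,
                               rh_base = 0.55, rh_temp_coupling = 0.02,
                               rh_noise_sd = 0.04,
                               wind_scale = 3, wind_shape = 2,
                               p_wet_given_wet = 0.5, p_wet_given_dry = 0.15,
                               rain_event_mean_mm = 5,
                               soil_infiltration_gain = 0.01,
                               soil10_decay_per_day = 0.05,
                               soil40_coupling = 0.1,
                               soil_floor = 0.08, soil_cap = 0.45) {
  fg_validate(days >= 1 && cadence > 0 && 1440 %% cadence == 0,
              "`days` must be >= 1 and `cadence` must divide 1440")
  fg_validate(p_wet_given_wet >= 0 && p_wet_given_wet <= 1 &&
                p_wet_given_dry >= 0 && p_wet_given_dry <= 1,
              "transition probabilities must be in [0, 1]")
  fg_validate(soil10_decay_per_day > 0 && soil10_decay_per_day < 1,
              "`soil10_decay_per_day` must be in (0, 1)")
  fg_validate(soil_cap > soil_floor && soil_floor >= 0 && soil_cap <= 1,
              "need 0 <= soil_floor < soil_cap <= 1")
  fg_validate(rain_event_mean_mm > 0 && soil_infiltration_gain >= 0,
              "rain and infiltration parameters must be non-negative")
  structure(as.list(environment()), class = "weather_gen_config")
}

#' Generate a synthetic station record series
#'
#' Produces one fixed-cadence sensor record per interval for
#' `config$days` days, reproducibly for a fixed seed. All outputs are
#' clipped to the station sensors' measuring ranges (temperature
#' [-55, 80] degC, humidity and soil VWC [0, 1], wind [0, 60] m/s with a
#' 0.3 m/s starting threshold, precipitation at most 4 mm/min).
#'
#' @param config a [weather_gen_config()].
#' @return data.frame of sensor records (internal units; see
#'   [read_sensor_csv()]).
#' @export
#' @examples
#' rec <- generate_weather(weather_gen_config(seed = 1, days = 2))
#' nrow(rec)  # 2 * 144
generate_weather <- function(config = weather_gen_config()) {
  fg_validate(inherits(config, "weather_gen_config"),
              "`config` must be a weather_gen_config")
  cfg <- config
  per_day <- as.integer(1440 / cfg$cadence)
  n <- cfg$days * per_day
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(cfg$seed, "weather"))

  start <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  ts <- start + (seq_len(n) - 1L) * cfg$cadence * 60
  hour <- (as.numeric(ts - start, units = "hours")) %% 24
  day_of <- rep(seq_len(cfg$days), each = per_day)

  # temperature: diurnal cycle peaking mid-afternoon + synoptic AR(1)
  # day-to-day offset + within-day AR(1) noise
  synoptic <- stats::filter(stats::rnorm(cfg$days, 0, 2.5 * sqrt(1 - 0.7^2)),
                            0.7, method = "recursive")
  phi <- 0.98
  noise <- stats::filter(stats::rnorm(n, 0, cfg$temp_noise_sd * sqrt(1 - phi^2)),
                         phi, method = "recursive")
  temp <- cfg$temp_mean +
    cfg$temp_diurnal_amp * cos(2 * pi * (hour - 14) / 24) +
    as.numeric(synoptic)[day_of] + as.numeric(noise)
  temp <- pmin(pmax(temp, -55), 80)

  # rain: daily two-state chain, amount ~ Exp(mean), one contiguous
  # intra-day event window with random sub-interval weights
  p_stat <- if (cfg$p_wet_given_dry == 0 && cfg$p_wet_given_wet == 0) 0 else
    cfg$p_wet_given_dry / (1 + cfg$p_wet_given_dry - cfg$p_wet_given_wet)
  wet <- logical(cfg$days)
  wet[1] <- stats::runif(1) < p_stat
  for (d in seq_len(cfg$days)[-1]) {
    p <- if (wet[d - 1L]) cfg$p_wet_given_wet else cfg$p_wet_given_dry
    wet[d] <- stats::runif(1) < p
  }
  precip <- numeric(n)
  for (d in which(wet)) {
    amount <- stats::rexp(1, 1 / cfg$rain_event_mean_mm)
    dur <- sample(3:24, 1)                       # 30 min .. 4 h event
    first <- sample(seq_len(per_day - dur + 1L), 1)
    w <- stats::runif(dur); w <- w / sum(w)
    at <- (d - 1L) * per_day + first + seq_len(dur) - 1L
    precip[at] <- precip[at] + amount * w
  }
  precip <- pmin(precip, 4 * cfg$cadence)  # sensor limit 4 mm/min

  # humidity: anti-correlated with temperature, wetter on rain intervals
  rh <- cfg$rh_base - cfg$rh_temp_coupling * (temp - cfg$temp_mean) +
    stats::rnorm(n, 0, cfg$rh_noise_sd) + 0.25 * (precip > 0)
  rh <- pmin(pmax(rh, 0), 1)

  wind <- stats::rweibull(n, cfg$wind_shape, cfg$wind_scale)
  wind <- pmin(ifelse(wind < 0.3, 0, wind), 60)  # starting threshold, range cap

  # soil bucket: fast infiltration, slow exponential relaxation
  keep10 <- (1 - cfg$soil10_decay_per_day)^(cfg$cadence / 1440)
  c40 <- cfg$soil40_coupling * cfg$cadence / 1440
  s10 <- numeric(n); s40 <- numeric(n)
  s10_prev <- cfg$soil_floor + 0.25 * (cfg$soil_cap - cfg$soil_floor)
  s40_prev <- s10_prev
  for (i in seq_len(n)) {
    s10_prev <- cfg$soil_floor + (s10_prev - cfg$soil_floor) * keep10 +
      cfg$soil_infiltration_gain * precip[i]
    s10_prev <- min(s10_prev, cfg$soil_cap)
    s40_prev <- s40_prev + c40 * (s10_prev - s40_prev)
    s10[i] <- s10_prev; s40[i] <- s40_prev
  }

  data.frame(timestamp = ts, station_id = cfg$station_id,
             air_temp = temp, rel_humidity = rh, wind_speed = wind,
             precip = precip, soil_vwc_10cm = s10, soil_vwc_40cm = s40)
}

# save/restore the global RNG state so generator calls do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Recover rain-process parameters from a record series
#'
#' Method-of-moments estimates of the wet-day frequency and the mean
#' wet-day rain amount, used to confirm that the generator hits its
#' configured targets.
#'
#' @param records sensor record data.frame (>= 30 days).
#' @param rain_day_threshold daily total (mm) defining a wet day.
#' @param tz time zone delimiting days.
#' @return list with `n_days`, `wet_frequency`, `mean_wet_day_rain`
#'   (NA if there are no wet days).
#' @export
recover_parameters <- function(records, rain_day_threshold = 0.1,
                               tz = "UTC") {
  day <- as.Date(records$timestamp, tz = tz)
  totals <- tapply(records$precip, day, sum)
  if (length(totals) < 30L) {
    fg_stop("need at least 30 days of records to estimate rain parameters",
            "firegrade_validation_error")
  }
  wet <- totals >= rain_day_threshold
  list(n_days = length(totals),
       wet_frequency = mean(wet),
       mean_wet_day_rain = if (any(wet)) mean(totals[wet]) else NA_real_)
}
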