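# The six component indices and the grade table.
#
# Components A, B, D are pure logistic curves of one daily input; C adds a
# dry-run bonus and a cap; E1 is a seasonal calendar value; E2 is the
# piecewise-linear humus-moisture correction. Scores are summed and binned
# onto the five-grade scale.

# ---- component indices ------------------------------------------------

#' Temperature index: daily maximum air temperature score
#'
#' Evaluates \eqn{Y'_A = 20 / (1 + e^{3.6421 - 0.2428 X_A})} (the published
#' reference curve) at the daily maximum air temperature.
#'
#' @param t_max daily maximum air temperature in degC (finite; may be
#'   vectorised).
#' @param params optional list with `alpha`, `beta`, `k` overriding the
#'   reference coefficients (e.g. one element of a [refit_builtin()] fit).
#' @return score strictly inside (0, 20), increasing in `t_max`.
#' @export
#' @examples
#' index_a(15)    # ~10, the curve midpoint
#' index_a(27.5)  # ~19.1
index_a <- function(t_max, params = reference_parameters()$A) {
  check_scalar(t_max, "t_max")
  eval_logistic(params$alpha, params$beta, params$k, t_max)
}

#' Humidity index: daily minimum relative humidity score
#'
#' Evaluates \eqn{Y'_B = 20 / (1 + e^{-6.0701 + 12.1403 X_B})} with
#' humidity as a fraction. Percent input is rejected (values above 1) to
#' guard against unit mistakes; convert at the I/O boundary.
#'
#' @param rh_min daily minimum relative humidity as a fraction in `[0, 1]`.
#' @param params optional coefficient override, see [index_a()].
#' @return score strictly inside (0, 20), decreasing in `rh_min`.
#' @export
#' @examples
#' index_b(0.25)  # dry air, ~19.1
#' index_b(0.75)  # humid air, ~0.9
index_b <- function(rh_min, params = reference_parameters()$B) {
  check_scalar(rh_min, "rh_min")
  fg_validate(all(rh_min >= 0 & rh_min <= 1),
              "`rh_min` must be a fraction in [0, 1] (not percent)")
  eval_logistic(params$alpha, params$beta, params$k, rh_min)
}

#' Precipitation index: daily precipitation and dry-run score
#'
#' For daily precipitation \eqn{X_C \le 10} mm the score is the logistic
#' term \eqn{10 / (1 + e^{-2.5545 + 0.8685 X_C})} plus `5 * t_run`; for
#' \eqn{X_C > 10} mm it is `5 * (t_run - 1)`. The result is clamped to
#' `[0, 50]` (the published cap is 50; the lower clamp keeps the
#' `t_run = 0` heavy-rain branch from going negative).
#'
#' The run counter `t_run` is, by default binding, the number of
#' consecutive preceding rain-free days ([update_runs()]); see the vignette
#' for the ambiguity in the source material around this counter.
#'
#' @param precip_mm daily precipitation total in mm (>= 0).
#' @param t_run consecutive-day run counter (integer >= 0).
#' @param params optional coefficient override for the logistic term.
#' @return score in `[0, 50]`.
#' @export
#' @examples
#' index_c(0.3, 0)   # ~9.1
#' index_c(0, 9)     # 50, clamped
#' index_c(12, 3)    # 10
index_c <- function(precip_mm, t_run, params = reference_parameters()$C) {
  check_scalar(precip_mm, "precip_mm")
  check_scalar(t_run, "t_run")
  fg_validate(all(precip_mm >= 0), "`precip_mm` must be >= 0")
  fg_validate(all(t_run >= 0), "`t_run` must be >= 0")
  raw <- ifelse(precip_mm <= 10,
                eval_logistic(params$alpha, params$beta, params$k, precip_mm) +
                  5 * t_run,
                5 * (t_run - 1))
  pmin(pmax(raw, 0), 50)
}

#' Wind index: daily maximum wind speed score
#'
#' Evaluates \eqn{Y'_D = 40 / (1 + e^{2.2844 - 0.2396 X_D})} at the daily
#' maximum wind speed in m/s. The sample points behind the curve are
#' wind-class midpoint speeds, so no Beaufort-class conversion is applied.
#'
#' @param wind_max daily maximum wind speed in m/s (>= 0).
#' @param params optional coefficient override.
#' @return score strictly inside (0, 40), increasing in `wind_max`.
#' @export
#' @examples
#' index_d(9.4)  # ~19.7
index_d <- function(wind_max, params = reference_parameters()$D) {
  check_scalar(wind_max, "wind_max")
  fg_validate(all(wind_max >= 0), "`wind_max` must be >= 0")
  eval_logistic(params$alpha, params$beta, params$k, wind_max)
}

#' Humus-layer soil moisture correction
#'
#' Piecewise-linear correction driven by the volumetric water content of
#' the humus (lowest litter) layer, measured by the 10 cm soil probe:
#' 0 below 5\% VWC, \eqn{4 - 80 x} between 5\% and 30\%, and -20 at and
#' above 30\%. Continuous at both breakpoints.
#'
#' @param humus_vwc volumetric water content as a fraction in `[0, 1]`.
#' @return score in `[-20, 0]`, non-increasing in `humus_vwc`.
#' @export
#' @examples
#' index_e2(0.04)   # 0   (too dry to buffer)
#' index_e2(0.175)  # -10
#' index_e2(0.35)   # -20 (saturated litter)
index_e2 <- function(humus_vwc) {
  check_scalar(humus_vwc, "humus_vwc")
  fg_validate(all(humus_vwc >= 0 & humus_vwc <= 1),
              "`humus_vwc` must be a fraction in [0, 1]")
  ifelse(humus_vwc < 0.05, 0,
         ifelse(humus_vwc < 0.30, 4 - 80 * humus_vwc, -20))
}

# ---- phenology --------------------------------------------------------

md_num <- function(md) {
  # "03-15" -> 315 for within-year comparison
  parts <- strsplit(md, "-", fixed = TRUE)[[1]]
  fg_validate(length(parts) == 2L,
              sprintf("malformed month-day '%s' (want 'MM-DD')", md))
  as.integer(parts[1]) * 100L + as.integer(parts[2])
}

in_md_range <- function(date, range) {
  v <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  lo <- md_num(range[[1]]); hi <- md_num(range[[2]])
  if (lo <= hi) v >= lo & v <= hi else v >= lo | v <= hi  # wraps new year
}

#' Phenology (vegetation cover) calendar configuration
#'
#' The coverage correction index takes a calendar value: `off_season_value`
#' outside the fire season, `fire_season_value` within it, and
#' `core_fire_season_value` in the core fire season. Defaults follow the
#' standard's empirical values (0 / 15 / 20) with a spring-and-autumn fire
#' season typical of northern China; all dates are configurable.
#'
#' @param off_season_value,fire_season_value,core_fire_season_value
#'   non-negative calendar scores (defaults 0, 15, 20).
#' @param fire_season_ranges list of `c(start, end)` month-day strings.
#' @param core_season_ranges list of `c(start, end)` month-day strings;
#'   every core range must lie inside some fire-season range.
#' @return object of class `phenology_config`.
#' @export
#' @examples
#' cfg <- phenology_config()
#' index_e1(as.Date("2017-04-01"), cfg)  # core season -> 20
phenology_config <- function(off_season_value = 0,
                             fire_season_value = 15,
                             core_fire_season_value = 20,
                             fire_season_ranges = list(c("03-01", "06-15"),
                                                       c("09-15", "11-30")),
                             core_season_ranges = list(c("03-15", "05-31"))) {
  vals <- c(off_season_value, fire_season_value, core_fire_season_value)
  fg_validate(all(is.finite(vals)) && all(vals >= 0),
              "phenology values must be non-negative")
  check_rng <- function(r) {
    fg_validate(length(r) == 2L, "each range must be c(start, end)")
    md_num(r[[1]]); md_num(r[[2]])
  }
  lapply(fire_season_ranges, check_rng)
  lapply(core_season_ranges, check_rng)
  # core ranges must sit inside the fire season (checked on a sample year)
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  in_any <- function(d, ranges)
    Reduce(`|`, lapply(ranges, function(r) in_md_range(d, r)), FALSE)
  core <- in_any(days, core_season_ranges)
  fire <- in_any(days, fire_season_ranges)
  fg_validate(!any(core & !fire),
              "core season ranges must lie inside the fire season ranges")
  structure(list(off_season_value = off_season_value,
                 fire_season_value = fire_season_value,
                 core_fire_season_value = core_fire_season_value,
                 fire_season_ranges = fire_season_ranges,
                 core_season_ranges = core_season_ranges),
            class = "phenology_config")
}

#' Phenology correction index for a date
#'
#' @param date a `Date` (or string coercible to one).
#' @param config a [phenology_config()].
#' @return the calendar score for that date (vectorised over `date`).
#' @export
index_e1 <- function(date, config = phenology_config()) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) fg_stop("malformed date", "firegrade_validation_error")
  in_any <- function(ranges)
    Reduce(`|`, lapply(ranges, function(r) in_md_range(d, r)),
           rep(FALSE, length(d)))
  ifelse(in_any(config$core_season_ranges), config$core_fire_season_value,
         ifelse(in_any(config$fire_season_ranges), config$fire_season_value,
                config$off_season_value))
}

# ---- composite and grade ----------------------------------------------

# Grade table: upper bounds of the integer composite index per grade.
# Real-valued totals are rounded half-up first, preserving the published
# integer thresholds (25/26, 50/51, 72/73, 90/91) verbatim.
grade_breaks <- c(25, 50, 72, 90)

round_half_up <- function(x) floor(x + 0.5)

#' Composite fire weather index and grade
#'
#' Sums the six component scores and classifies the total onto the
#' five-grade scale: I for a (rounded) total of at most 25, II for 26--50,
#' III for 51--72, IV for 73--90, V for 91 and above. Rounding is half-up
#' to the nearest integer.
#'
#' @param y_a,y_b,y_c,y_d,y_e1,y_e2 component scores (vectorised).
#' @return data.frame with columns `total` (the unrounded sum) and
#'   `grade` (integer 1--5).
#' @export
#' @examples
#' composite_and_grade(19.1, 19.1, 50, 37.4, 20, 0)  # grade 5
composite_and_grade <- function(y_a, y_b, y_c, y_d, y_e1, y_e2) {
  total <- y_a + y_b + y_c + y_d + y_e1 + y_e2
  r <- round_half_up(total)
  grade <- 1L + findInterval(r, grade_breaks + 1L)
  data.frame(total = total, grade = as.integer(grade))
}
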