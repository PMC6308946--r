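#' Construct a step-interval sample set
#'
#' A sample set is the list of (interval midpoint, score) pairs that the
#' operational standard assigns to one meteorological index, together with
#' the saturation score K of that index. The logistic index curves are
#' fitted to these pairs with K held fixed.
#'
#' @param index_id one of `"A"` (daily maximum air temperature, degC),
#'   `"B"` (daily minimum relative humidity, fraction), `"C"` (daily
#'   precipitation, mm), `"D"` (daily maximum wind speed, m/s).
#' @param x numeric vector of interval midpoints, strictly monotone.
#' @param y numeric vector of scores, same length as `x`, all in `[0, k]`.
#' @param k saturation score of the index (> 0).
#' @param x_units unit label carried along for printing.
#' @return an object of class `step_sample_set`.
#' @seealso [builtin_sample_sets()] for the four bundled sets.
#' @export
#' @examples
#' step_sample_set("A", x = c(2.5, 7.5, 12.5), y = c(0, 4, 8), k = 20,
#'                 x_units = "degC")
step_sample_set <- function(index_id, x, y, k, x_units = "") {
  fg_validate(is.character(index_id) && length(index_id) == 1L,
              "`index_id` must be a single string")
  fg_validate(length(x) > 0L && length(x) == length(y),
              "`x` and `y` must be non-empty and of equal length")
  fg_validate(is.numeric(k) && length(k) == 1L && is.finite(k) && k > 0,
              "`k` must be a positive number")
  fg_validate(all(is.finite(x)) && all(is.finite(y)),
              "`x` and `y` must be finite")
  fg_validate(all(y >= 0 & y <= k), "all scores must lie in [0, k]")
  d <- diff(x)
  fg_validate(all(d > 0) || all(d < 0),
              "`x` must be strictly monotone")
  structure(
    list(index_id = index_id, x = as.numeric(x), y = as.numeric(y),
         k = as.numeric(k), x_units = x_units),
    class = "step_sample_set"
  )
}

#' @export
print.step_sample_set <- function(x, ...) {
  cat(sprintf("Step sample set for index %s (K = %g, x in %s)\n",
              x$index_id, x$k, if (nzchar(x$x_units)) x$x_units else "?"))
  print(data.frame(x = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}

#' The four bundled step-interval sample sets
#'
#' Returns the (midpoint, score) tables of the operational fire-danger
#' standard for the four meteorological indices, as published with the
#' logistic smoothing method:
#' \describe{
#'   \item{A}{daily maximum air temperature (degC), K = 20}
#'   \item{B}{daily minimum relative humidity (stored as a fraction;
#'     the published table is in percent), K = 20}
#'   \item{C}{daily precipitation amount (mm) for the logistic part of the
#'     precipitation index, K = 10}
#'   \item{D}{daily maximum wind speed (m/s, wind-class midpoints), K = 40}
#' }
#'
#' @return named list of [step_sample_set] objects with names
#'   `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
#' @examples
#' sets <- builtin_sample_sets()
#' sets$A$k          # 20
#' length(sets$D$x)  # 9
builtin_sample_sets <- function() {
  list(
    A = step_sample_set("A",
      x = c(2.5, 7.5, 12.5, 17.5, 22.5, 27.5),
      y = c(0, 4, 8, 12, 16, 20), k = 20, x_units = "degC"),
    B = step_sample_set("B",
      x = c(0.75, 0.65, 0.55, 0.45, 0.35, 0.25),
      y = c(0, 4, 8, 12, 16, 20), k = 20, x_units = "fraction RH"),
    C = step_sample_set("C",
      x = c(0.3, 0.9, 2.0, 3.5, 5, 7.5),
      y = c(10, 8, 6, 4, 2, 0), k = 10, x_units = "mm precipitation"),
    D = step_sample_set("D",
      x = c(0.1, 0.9, 2.5, 6.7, 9.4, 12.3, 15.5, 19.0, 20.7),
      y = c(0, 5, 10, 15, 20, 25, 30, 35, 40), k = 40, x_units = "m/s wind")
  )
}

#' Published reference coefficients of the index curves
#'
#' The logistic index curves as published for operational use:
#' \deqn{Y'_i = K_i / (1 + e^{\alpha_i + \beta_i X_i}).}
#' These are the coefficients the assessment functions [index_a()] ...
#' [index_d()] evaluate by default. Note that refitting the bundled sample
#' sets by unweighted nonlinear least squares ([fit_logistic()]) lands on a
#' nearby but not identical optimum; see the package vignette.
#'
#' @return named list with elements `A`, `B`, `C`, `D`, each a list with
#'   `alpha`, `beta`, `k`.
#' @export
#' @examples
#' reference_parameters()$A
reference_parameters <- function() {
  list(
    A = list(alpha =  3.6421, beta =  -0.2428, k = 20),
    B = list(alpha = -6.0701, beta =  12.1403, k = 20),
    C = list(alpha = -2.5545, beta =   0.8685, k = 10),
    D = list(alpha =  2.2844, beta =  -0.2396, k = 40)
  )
}

#' Load sample sets from a configuration list
#'
#' Allows the bundled step tables to be overridden from a YAML/JSON
#' configuration. Each entry must provide `x`, `y` and `k` (and may provide
#' `x_units`); indices not mentioned keep their bundled tables.
#'
#' @param config named list, e.g. the result of `yaml::read_yaml()` on a
#'   file with a `sample_sets:` section.
#' @return named list of [step_sample_set] objects.
#' @export
sample_sets_from_config <- function(config) {
  sets <- builtin_sample_sets()
  if (is.null(config)) return(sets)
  fg_validate(is.list(config), "`config` must be a list")
  for (id in names(config)) {
    fg_validate(id %in% names(sets),
                sprintf("unknown index id '%s' in sample set config", id))
    entry <- config[[id]]
    sets[[id]] <- step_sample_set(
      id, x = unlist(entry$x), y = unlist(entry$y), k = entry$k,
      x_units = if (!is.null(entry$x_units)) entry$x_units
                else sets[[id]]$x_units)
  }
  sets
}
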