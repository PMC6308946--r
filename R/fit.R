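# Logistic curve fitting for the step-interval sample sets.
#
# The curve is Y = K / (1 + exp(alpha + beta * X)) with K fixed by the
# standard, so only (alpha, beta) are estimated. Endpoint scores y = 0 and
# y = K make a pure logit linearisation undefined, so starting values come
# from an ordinary regression on the logit of y clipped into
# [0.01 K, 0.99 K]; Levenberg-Marquardt then minimises the untransformed
# residual sum of squares.

eval_logistic <- function(alpha, beta, k, x) k / (1 + exp(alpha + beta * x))

#' Fit a logistic index curve to a step-interval sample set
#'
#' Minimises \eqn{\sum_j (y_j - K/(1+e^{\alpha+\beta x_j}))^2} over
#' \eqn{(\alpha, \beta)} with K taken from the sample set (never
#' estimated), by Levenberg-Marquardt nonlinear least squares. Starting
#' values are obtained from a linear regression of
#' \eqn{\log(K/y - 1)} on x after clipping y into `[0.01 K, 0.99 K]`.
#'
#' @param samples a [step_sample_set].
#' @param max_iter maximum Levenberg-Marquardt iterations (default 200).
#' @return object of class `logistic_fit`: a list with `index_id`,
#'   `alpha`, `beta`, `k`, `r_squared`, `fitted_values` and `samples`.
#' @section Errors:
#' Degenerate input (all scores equal) raises a
#' `firegrade_degenerate_error`; failure to converge within `max_iter`
#' iterations raises a `firegrade_fit_error`.
#' @export
#' @examples
#' fit <- fit_logistic(builtin_sample_sets()$A)
#' c(fit$alpha, fit$beta, fit$r_squared)
fit_logistic <- function(samples, max_iter = 200L) {
  fg_validate(inherits(samples, "step_sample_set"),
              "`samples` must be a step_sample_set")
  fg_validate(length(samples$x) >= 3L,
              "at least 3 sample pairs are required")
  x <- samples$x; y <- samples$y; k <- samples$k
  if (diff(range(y)) == 0) {
    fg_stop("all scores in the sample set are equal; the curve is not identifiable",
            "firegrade_degenerate_error")
  }
  y_clip <- pmin(pmax(y, 0.01 * k), 0.99 * k)
  start <- stats::coef(stats::lm(log(k / y_clip - 1) ~ x))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ k / (1 + exp(alpha + beta * x)),
      data = data.frame(x = x, y = y, k = k),
      start = list(alpha = unname(start[1]), beta = unname(start[2])),
      control = minpack.lm::nls.lm.control(maxiter = as.integer(max_iter))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    info <- fit$convInfo
    if (!is.null(info) && isFALSE(info$isConv)) {
      fg_stop(sprintf("logistic fit did not converge within %d iterations",
                      max_iter), "firegrade_fit_error")
    }
    co <- stats::coef(fit)
  } else {
    # LM can refuse a start whose residuals already vanish (singular
    # gradient); minimise the same SSE by quasi-Newton from that start
    sse <- function(p) sum((y - eval_logistic(p[1], p[2], k, x))^2)
    o <- stats::optim(unname(start), sse, method = "BFGS",
                      control = list(maxit = as.integer(max_iter),
                                     reltol = 1e-14))
    if (o$convergence != 0) {
      fg_stop("logistic fit failed to converge", "firegrade_fit_error")
    }
    co <- c(alpha = o$par[1], beta = o$par[2])
  }
  out <- structure(
    list(index_id = samples$index_id,
         alpha = unname(co[["alpha"]]), beta = unname(co[["beta"]]),
         k = k, r_squared = NA_real_,
         fitted_values = eval_logistic(co[["alpha"]], co[["beta"]], k, x),
         samples = samples),
    class = "logistic_fit")
  out$r_squared <- r_squared(out, samples)
  out
}

#' Coefficient of determination of a logistic fit
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}, with the
#' total sum of squares about the mean score of the sample set.
#'
#' @param fit a `logistic_fit` (or any list with `alpha`, `beta`, `k`).
#' @param samples the [step_sample_set] to evaluate on; its `k` must equal
#'   the fit's.
#' @return numeric scalar in \eqn{(-\infty, 1]}.
#' @export
#' @examples
#' sets <- builtin_sample_sets()
#' r_squared(fit_logistic(sets$A), sets$A)
r_squared <- function(fit, samples) {
  fg_validate(inherits(samples, "step_sample_set"),
              "`samples` must be a step_sample_set")
  fg_validate(isTRUE(all.equal(fit$k, samples$k)),
              "`fit$k` must equal `samples$k`")
  y <- samples$y
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    fg_stop("zero total sum of squares: all scores equal",
            "firegrade_degenerate_error")
  }
  yhat <- eval_logistic(fit$alpha, fit$beta, fit$k, samples$x)
  1 - sum((y - yhat)^2) / ss_tot
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic index curve %s: Y = %g / (1 + exp(%.5f %+.5f X)), R^2 = %.5f\n",
    x$index_id, x$k, x$alpha, x$beta, x$r_squared))
  invisible(x)
}

#' Refit all bundled sample sets
#'
#' Fits the logistic curve to each of the four bundled step tables and
#' returns the coefficients and goodness of fit in one table.
#'
#' @param sets named list of [step_sample_set] objects; defaults to
#'   [builtin_sample_sets()].
#' @return data.frame with columns `index_id`, `alpha`, `beta`, `k`,
#'   `r_squared`, one row per set, plus the fits in attribute `"fits"`.
#' @export
#' @examples
#' refit_builtin()
refit_builtin <- function(sets = builtin_sample_sets()) {
  fits <- lapply(sets, fit_logistic)
  out <- data.frame(
    index_id = vapply(fits, `[[`, "", "index_id"),
    alpha = vapply(fits, `[[`, 0, "alpha"),
    beta = vapply(fits, `[[`, 0, "beta"),
    k = vapply(fits, `[[`, 0, "k"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    row.names = NULL)
  attr(out, "fits") <- fits
  out
}

#' Export fitted index-curve parameters as JSON
#'
#' @param fits list of `logistic_fit` objects (e.g.
#'   `attr(refit_builtin(), "fits")`) or the data.frame returned by
#'   [refit_builtin()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_fitted_parameters <- function(fits, path) {
  if (is.data.frame(fits)) {
    recs <- lapply(seq_len(nrow(fits)), function(i) as.list(fits[i, ]))
    names(recs) <- fits$index_id
  } else {
    recs <- lapply(fits, function(f)
      list(index_id = f$index_id, alpha = f$alpha, beta = f$beta,
           k = f$k, r_squared = f$r_squared))
    names(recs) <- vapply(fits, `[[`, "", "index_id")
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
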