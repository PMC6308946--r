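# Statement generation: per-period aggregates of the monitoring channels
# plus fire-grade counts, the tabular reports a station operator reads.

period_key <- function(date, period) {
  switch(period,
         daily = format(date, "%Y-%m-%d"),
         monthly = format(date, "%Y-%m"),
         annual = format(date, "%Y"))
}

#' Build a monitoring statement
#'
#' Aggregates daily summaries and assessments into a daily, monthly or
#' annual statement: per-period means/extremes/totals of each channel and
#' the count of days in each fire weather grade. Column order is fixed, so
#' re-running on identical input yields a byte-identical file.
#'
#' @param assessments data.frame from [assess_series()].
#' @param summaries data.frame from [aggregate_daily()].
#' @param period one of `"daily"`, `"monthly"`, `"annual"`.
#' @param path optional CSV path; when given the statement is written
#'   there.
#' @return the statement data.frame (invisibly when `path` is given).
#' @export
write_statement <- function(assessments, summaries,
                            period = c("daily", "monthly", "annual"),
                            path = NULL) {
  period <- match.arg(period)
  if (is.null(summaries) || nrow(summaries) == 0L ||
      is.null(assessments) || nrow(assessments) == 0L) {
    fg_stop("cannot build a statement from empty input",
            "firegrade_empty_report_error")
  }
  s <- summaries[summaries$n_records > 0L, , drop = FALSE]
  key_s <- period_key(s$date, period)
  agg <- function(v, f) as.numeric(tapply(v, key_s, f))
  keys <- sort(unique(key_s))
  out <- data.frame(
    period = keys,
    days = as.integer(table(factor(key_s, levels = keys))),
    t_mean = agg(s$t_max, mean), t_max = agg(s$t_max, max),
    rh_min = agg(s$rh_min, min),
    precip_total = agg(s$precip_total, sum),
    wind_max = agg(s$wind_max, max),
    vwc10_mean = agg(s$humus_vwc, mean),
    vwc40_mean = agg(s$soil40_vwc, mean))
  key_a <- period_key(assessments$date, period)
  for (g in 1:5) {
    cnt <- tapply(assessments$grade == g, key_a, sum)
    out[[paste0("grade", g, "_days")]] <-
      as.integer(ifelse(is.na(cnt[keys]), 0L, cnt[keys]))
  }
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) round(v, 4))
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
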