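# Daily aggregation: summaries, gap policy, run counters, scoring.

test_that("summarize_day computes the daily index inputs", {
  rec <- make_day_records(air_temp = 10)
  s <- summarize_day(rec)
  expect_equal(s$t_max, 10)
  expect_equal(s$n_records, 144L)
  expect_false(s$gap_flag)
  # precipitation totals are sums over the intervals
  p <- rep(0, 144); p[30:34] <- 0.2
  s2 <- summarize_day(make_day_records(precip = p))
  expect_equal(s2$precip_total, 1.0)
  # extremes and means
  temps <- 5 + 10 * sin(seq(0, pi, length.out = 144))
  s3 <- summarize_day(make_day_records(air_temp = temps,
                                       rel_humidity = seq(0.9, 0.3, length.out = 144)))
  expect_equal(s3$t_max, max(temps))
  expect_equal(s3$rh_min, 0.3)
  expect_error(summarize_day(rec[0, ]), class = "firegrade_empty_day_error")
})

test_that("aggregation is invariant to row order and duplication", {
  rec <- make_day_records(air_temp = rnorm(144, 10),
                          precip = rpois(144, 1) * 0.1)
  s <- summarize_day(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(summarize_day(shuffled), s)
  duplicated <- rbind(rec, rec[40:60, ])
  expect_equal(summarize_day(duplicated), s)
})

test_that("short gaps are interpolated, long gaps flag the day", {
  # 20-minute hole around a ramp: the missing soil reading sits on the
  # line between its neighbours, so the daily mean is the hand-computed
  # mean of the explicitly filled series
  vwc <- rep(0.10, 144); vwc[49] <- 0.10; vwc[51] <- 0.30
  rec <- make_day_records(soil_vwc_10cm = vwc)
  rec <- rec[-50, ]  # one missing interval -> 20 min between neighbours
  s <- summarize_day(rec)
  expect_false(s$gap_flag)
  filled <- vwc; filled[50] <- (0.10 + 0.30) / 2
  expect_equal(s$humus_vwc, mean(filled), tolerance = 1e-12)
  # a 40-minute hole exceeds the 30-minute bridge and flags the day
  rec2 <- make_day_records()[-(50:53), ]
  s2 <- summarize_day(rec2)
  expect_true(s2$gap_flag)
  expect_equal(s2$t_max, 10)  # statistics still computed from what exists
})

test_that("coverage below the threshold raises a condition carrying the partial summary", {
  rec <- make_day_records()[1:100, ]  # 100/144 < 0.8
  err <- tryCatch(summarize_day(rec), firegrade_low_coverage_error = identity)
  expect_s3_class(err, "firegrade_low_coverage_error")
  expect_equal(err$summary$t_max, 10)
  expect_true(err$summary$gap_flag)
})

test_that("run counters count consecutive dry and wet days", {
  s <- run_summaries(c(0, 0, 5, 0))
  expect_equal(s$dry_run, c(1L, 2L, 0L, 1L))
  expect_equal(s$wet_run, c(0L, 0L, 1L, 0L))
  first <- update_runs(NULL, make_summary("2017-04-01", precip_total = 0))
  expect_equal(first$dry_run, 1L)
  # non-consecutive days are refused
  a <- update_runs(NULL, make_summary("2017-04-01"))
  expect_error(update_runs(a, make_summary("2017-04-03")),
               class = "firegrade_sequence_error")
})

test_that("exactly one run counter is positive, resetting at every crossing", {
  set.seed(11)
  for (rep in 1:5) {
    precip <- ifelse(runif(60) < 0.3, rexp(60, 1 / 4), 0)
    s <- run_summaries(precip)
    expect_true(all((s$dry_run > 0) != (s$wet_run > 0)))
    # reference counter computed independently
    wet <- precip >= 0.1
    ref_dry <- integer(60); ref_wet <- integer(60)
    for (i in seq_len(60)) {
      if (wet[i]) {
        ref_wet[i] <- if (i > 1) ref_wet[i - 1] + 1L else 1L
      } else {
        ref_dry[i] <- if (i > 1) ref_dry[i - 1] + 1L else 1L
      }
    }
    expect_equal(s$dry_run, ref_dry)
    expect_equal(s$wet_run, ref_wet)
  }
})

test_that("aggregate_daily threads runs through a series and resets at missing days", {
  rain <- rep(0, 144); rain[60:71] <- 0.5
  days <- rbind(make_day_records("2017-04-01"),
                make_day_records("2017-04-02", precip = rain),
                make_day_records("2017-04-04"))
  daily <- aggregate_daily(days)
  expect_equal(nrow(daily), 4L)  # the missing Apr 3 appears as a flagged row
  expect_equal(daily$dry_run[1:2], c(1L, 0L))
  expect_equal(daily$wet_run[2], 1L)
  expect_equal(daily$n_records[3], 0L)
  expect_equal(daily$dry_run[4], 1L)  # counters restart after the hole
})

test_that("a rain-soaked day scores lower than the dry day before it", {
  s <- run_summaries(c(0, 12), t_max = 15, rh_min = 0.45, wind_max = 4,
                     humus_vwc = 0.1)
  s$humus_vwc[2] <- 0.35  # soaked litter on the rain day
  s$rh_min[2] <- 0.85
  a <- assess_series(s)
  expect_equal(a$y_e2[2], -20)
  expect_lt(a$total[2], a$total[1])
  expect_equal(a$total, a$y_a + a$y_b + a$y_c + a$y_d + a$y_e1 + a$y_e2)
})

test_that("benign weather gives Grade I and severe fire weather Grade V", {
  benign <- run_summaries(20, t_max = 0, rh_min = 1.0, wind_max = 0,
                          humus_vwc = 0.4)
  expect_equal(assess_series(benign)$grade, 1L)
  severe <- run_summaries(rep(0, 9), t_max = 27.5, rh_min = 0.25,
                          wind_max = 20.7, humus_vwc = 0.03)
  a <- assess_series(severe)
  expect_equal(a$grade[9], 5L)
  expect_gt(a$total[9], 140)  # ~19.1 + 19.1 + 50 + 37.4 + 20 + 0
})

test_that("a multi-day rain block scores below the surrounding dry days", {
  precip <- c(0, 0, 0, 15, 18, 12, 0, 0, 0)
  s <- run_summaries(precip, t_max = 18, rh_min = 0.4, wind_max = 5,
                     humus_vwc = 0.12)
  s$humus_vwc[4:6] <- 0.33  # saturated litter during the block
  a <- assess_series(s)
  expect_true(max(a$total[4:6]) < min(a$total[c(3, 7)]))
})

test_that("unset run counters are a state error", {
  s <- make_summary("2017-04-01")
  expect_error(assess_series(s), class = "firegrade_state_error")
})
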