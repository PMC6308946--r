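# Component index curves: frozen direct evaluations of the published
# reference coefficients, bounds, monotonicity and the grade table.

test_that("temperature index matches direct evaluation of the reference curve", {
  expect_equal(index_a(15), 9.9995, tolerance = 1e-4)     # curve midpoint
  expect_equal(index_a(27.5), 19.08252, tolerance = 1e-5)
  expect_lt(index_a(-40), 0.001)                          # saturation tail
  grid <- seq(-50, 60, by = 0.5)
  v <- index_a(grid)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 20))
  expect_error(index_a(NaN), class = "firegrade_validation_error")
})

test_that("humidity index matches direct evaluation and rejects percent input", {
  expect_equal(index_b(0.75), 0.9172806, tolerance = 1e-5)
  expect_equal(index_b(0.25), 19.08263, tolerance = 1e-5)
  expect_equal(index_b(0.50), 10.0, tolerance = 1e-3)     # exponent ~ 0
  v <- index_b(seq(0, 1, by = 0.01))
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v < 20))
  expect_error(index_b(45), class = "firegrade_validation_error")
})

test_that("precipitation index follows both branches and the 0..50 clamp", {
  expect_equal(index_c(0.3, 0), 9.083747, tolerance = 1e-5)
  expect_equal(index_c(0, 9), 50)            # logistic(0) + 45, clamped
  expect_equal(index_c(12, 3), 10)           # heavy-rain branch 5(t-1)
  expect_equal(index_c(12, 0), 0)            # lower clamp on 5(t-1) at t=0
  # logistic part strictly decreasing in the precipitation amount
  v <- index_c(seq(0, 10, by = 0.25), 0)
  expect_true(all(diff(v) < 0))
  # bounds over a random sweep
  set.seed(7)
  p <- runif(200, 0, 30); t <- sample(0:15, 200, replace = TRUE)
  out <- mapply(index_c, p, t)
  expect_true(all(out >= 0 & out <= 50))
  expect_error(index_c(-1, 0), class = "firegrade_validation_error")
  expect_error(index_c(1, -1), class = "firegrade_validation_error")
})

test_that("wind index matches direct evaluation and increases with wind", {
  expect_equal(index_d(0.1), 3.778109, tolerance = 1e-5)
  expect_equal(index_d(9.4), 19.67843, tolerance = 1e-5)
  expect_lt(index_d(0), index_d(60))
  v <- index_d(seq(0, 60, by = 1))
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 40))
  expect_error(index_d(-2), class = "firegrade_validation_error")
})

test_that("humus moisture correction is piecewise linear and continuous", {
  expect_equal(index_e2(0.04), 0)
  expect_equal(index_e2(0.175), -10)
  expect_equal(index_e2(0.35), -20)
  # continuity at both breakpoints
  expect_lt(abs(index_e2(0.05) - index_e2(0.05 - 1e-12)), 1e-9)
  expect_lt(abs(index_e2(0.30) - index_e2(0.30 - 1e-12)), 1e-9)
  expect_equal(index_e2(0.05), 0)
  expect_equal(index_e2(0.30), -20)
  v <- index_e2(seq(0, 1, by = 0.005))
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= -20 & v <= 0))
  expect_error(index_e2(1.5), class = "firegrade_validation_error")
})

test_that("phenology calendar scores by season", {
  cfg <- phenology_config()
  expect_equal(index_e1(as.Date("2017-04-15"), cfg), 20)  # core season
  expect_equal(index_e1(as.Date("2017-06-10"), cfg), 15)  # fire season only
  expect_equal(index_e1(as.Date("2017-10-01"), cfg), 15)  # autumn season
  expect_equal(index_e1(as.Date("2017-07-20"), cfg), 0)   # off season
  expect_error(index_e1("not-a-date"), class = "firegrade_validation_error")
  # core ranges must nest inside the fire season
  expect_error(phenology_config(core_season_ranges = list(c("07-01", "07-31"))),
               class = "firegrade_validation_error")
})

test_that("composite index sums components and grades follow the table", {
  expect_equal(composite_and_grade(0, 0, 0, 0, 0, 0),
               data.frame(total = 0, grade = 1L))
  expect_equal(composite_and_grade(10, 10, 20, 10, 10, 0)$grade, 3L)  # 60
  expect_equal(composite_and_grade(19, 19, 50, 37, 20, -50)$total, 95)
  expect_equal(composite_and_grade(19, 19, 50, 37, 20, -50)$grade, 5L)
  # rounding half-up before the integer thresholds
  expect_equal(composite_and_grade(25.4, 0, 0, 0, 0, 0)$grade, 1L)
  expect_equal(composite_and_grade(25.6, 0, 0, 0, 0, 0)$grade, 2L)
  expect_equal(composite_and_grade(90.5, 0, 0, 0, 0, 0)$grade, 5L)
  # a negative total (soil correction dominating) is still Grade I
  expect_equal(composite_and_grade(0, 0, 0, 0, 0, -20)$grade, 1L)
  # grade is a non-decreasing step function of the total
  totals <- seq(-25, 150, by = 0.25)
  g <- composite_and_grade(totals, 0, 0, 0, 0, 0)$grade
  expect_true(all(diff(g) >= 0))
  expect_setequal(unique(g), 1:5)
})
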