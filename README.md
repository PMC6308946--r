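# firegrade

Daily forest fire weather grades (I–V) from environmental station time
series, for forest fire protection staff and for anyone building or
testing automatic fire-warning pipelines on microclimate monitoring data.

Operational fire danger rating in China scores four daily meteorological
inputs on stepped intervals, so near-identical weather can receive
visibly different danger scores. `firegrade` replaces each step table
with a logistic curve

    Y'_i = K_i / (1 + exp(alpha_i + beta_i * X_i)),   i in {A, B, C, D}

fitted to the table's (interval midpoint, score) pairs with the
saturation score `K_i ∈ {20, 20, 10, 40}` held fixed, and corrects the
phenology term with the volumetric water content of the humus (litter)
layer measured by a 10 cm soil probe:

    Y'_E2 = 0            if x < 5%
          = 4 - 80 x     if 5% <= x < 30%
          = -20          if x >= 30%

The composite index `Y = Y'_A + Y'_B + Y'_C + Y'_D + Y'_E1 + Y'_E2` is
rounded half-up and binned: Grade I (≤ 25), II (26–50), III (51–72),
IV (73–90), V (≥ 91). The package covers the whole path from raw
10-minute sensor records (CSV) to graded days and statements, plus a
stochastic station-weather generator and a 72-byte telemetry frame codec
with a lossy-channel simulator so the pipeline can be exercised without
field data. See the vignette `vignettes/fire-weather-grades.Rmd` for the
model, the aggregation rules and the design decisions.

## Worked example

```r
library(firegrade)

rec   <- generate_weather(weather_gen_config(seed = 42, days = 14))
daily <- aggregate_daily(rec)
a     <- assess_series(daily)
a[, c("date", "y_a", "y_b", "y_c", "y_d", "y_e1", "y_e2", "total", "grade")]
```

```
         date  y_a  y_b   y_c  y_d y_e1   y_e2 total grade
3  2017-03-03 12.8 15.8  8.31 16.8   15  -9.55  59.2     3
...
12 2017-03-12 15.6 17.4 39.28 14.2   15 -10.41  91.1     5
13 2017-03-13 16.2 17.9 44.28 12.2   15 -10.01  95.6     5
14 2017-03-14 14.4 16.4  3.57 13.8   15 -12.14  51.1     3
```

A rain spell starts on 3 March: the precipitation score `y_c` drops to
its logistic-only level, the wetted litter pushes `y_e2` toward −13, and
the days stay Grade III. From 7 March a dry run builds `y_c` by 5 points
per day until the composite crosses 91 — Grade V, the highest fire
danger — on 12 March; the 3.6 mm of rain on 14 March resets the run and
drops the day back to Grade III.

Refitting the bundled step tables prints the least-squares curves and
their goodness of fit:

```r
refit_builtin()
#>   index_id   alpha     beta  k r_squared
#> 1        A  3.1883 -0.21256 20   0.98240
#> 2        B -5.3139 10.62781 20   0.98240
#> 3        C -2.2675  0.77993 10   0.96963
#> 4        D  2.1190 -0.22221 40   0.97109
```

These differ from the operational reference coefficients
(`reference_parameters()`), which are not the least-squares optimum of
their own tables; the vignette discusses the discrepancy. Daily
assessment uses the reference set by default.

The same pipeline is available from a shell via the thin wrapper in
`inst/scripts/firegrade`:

```sh
firegrade simulate  --days 92 --seed 1 --out sensor.csv
firegrade aggregate --in sensor.csv --out daily.csv
firegrade assess    --in daily.csv --out assessed.csv
firegrade report    --assessments assessed.csv --summaries daily.csv \
                    --period monthly --out statement.csv
```

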