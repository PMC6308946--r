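---
title: "Computing forest fire weather grades from station time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing forest fire weather grades from station time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firegrade)
```

## The problem and the model

Operational forest fire danger rating in China scores four daily
meteorological inputs — the daily maximum air temperature $X_A$, the daily
minimum relative humidity $X_B$, the daily precipitation situation $X_C$,
and the daily maximum wind $X_D$ — on stepped intervals, adds a phenology
correction $E$, and bins the sum into five fire weather grades I–V. The
step tables have a well-known artefact: two days whose weather differs by
a fraction of a degree can land in different steps and receive visibly
different danger scores.

This package smooths each step table with a logistic curve

$$Y'_i = \frac{K_i}{1 + e^{\alpha_i + \beta_i X_i}}, \qquad
  i \in \{A, B, C, D\},$$

where $K_i \in \{20, 20, 10, 40\}$ is the saturation score fixed by the
standard and $(\alpha_i, \beta_i)$ are fitted to the (interval midpoint,
score) pairs of the standard by unweighted nonlinear least squares
(`fit_logistic()`; the four tables ship as `builtin_sample_sets()`). The
exponent is written exactly as $\alpha + \beta x$, so $\beta$ is negative
for the increasing curves (temperature, wind).

The precipitation index combines the logistic term with a run counter
$t$:

$$Y'_C = \begin{cases}
  \dfrac{10}{1 + e^{-2.5545 + 0.8685\,X_C}} + 5t & X_C \le 10\ \text{mm}\\[1ex]
  5(t - 1) & X_C > 10\ \text{mm}
\end{cases}$$

clamped to $[0, 50]$. The phenology correction has two parts: a calendar
value $Y'_{E1}$ (0 outside the fire season, 15 in it, 20 in the core fire
season; `phenology_config()`) and a litter-layer soil moisture correction

$$Y'_{E2} = \begin{cases}
  0 & x < 5\%\\
  4 - 80x & 5\% \le x < 30\%\\
  -20 & x \ge 30\%
\end{cases}$$

driven by the volumetric water content $x$ of the humus layer, which a
10 cm soil moisture probe measures directly. $Y'_{E2}$ is continuous at
both breakpoints and rewards saturated litter with a full −20 points.
The composite index is

$$Y = Y'_A + Y'_B + Y'_C + Y'_D + Y'_{E1} + Y'_{E2},$$

rounded half-up and classified as Grade I ($\le 25$), II (26–50),
III (51–72), IV (73–90) or V ($\ge 91$).

## Fitting: algorithm and a caution about the reference coefficients

`fit_logistic()` minimises the untransformed residual sum of squares
$\sum_j (y_j - K/(1+e^{\alpha+\beta x_j}))^2$ with K fixed, by
Levenberg–Marquardt. Because the endpoint scores $y = 0$ and $y = K$ make
the logit transform undefined, starting values come from an ordinary
regression of $\log(K/y - 1)$ on $x$ after clipping $y$ into
$[0.01K, 0.99K]$. If the Levenberg–Marquardt step refuses a start whose
residuals already vanish (exactly generated data), a quasi-Newton
minimisation of the same objective finishes the job. Degenerate inputs
(all scores equal) and non-convergence raise typed errors.

```{r}
refit_builtin()
```

The package also ships the operational reference coefficients
(`reference_parameters()`), and the daily assessment uses those by
default. The two sets are deliberately kept distinct, for a reason worth
stating plainly: **the reference coefficients are not the least-squares
optimum of the step tables they are said to be fitted from.** For the
temperature table the unweighted optimum is $\alpha = 3.1883$,
$\beta = -0.2126$ with $R^2 = 0.9824$, while the operational reference
lists $\alpha = 3.6421$, $\beta = -0.2428$ with $R^2 = 0.9771$ — a curve
with the same midpoint ($-\alpha/\beta = 15.0$) but a steeper slope and,
necessarily, a *lower* $R^2$ than the optimum. The reference values are
internally consistent (evaluating them on the table reproduces their
quoted $R^2$ exactly), so they stem from some other fitting procedure we
could not identify; we probed logit-scale regression under several
endpoint treatments, robust (L1 and minimax) losses, and free-K fits,
none of which reproduces them across all four tables. Related, the
quoted $R^2$ values for the precipitation and wind curves appear to be
swapped: the reference wind coefficients evaluated on the wind table give
$R^2 = 0.9691$, the value attributed to precipitation. Comparisons in the
test suite therefore treat those two values as an unordered pair.

An internal consistency check that does not depend on any quoted number:
the humidity table is the temperature table under the affine map
$x \mapsto 0.80 - 0.02x$, so a correct fitter must return
$\beta_B = \beta_A / (-0.02)$ and identical $R^2$ for the two tables.
`fit_logistic()` satisfies this to floating tolerance.

## Daily aggregation

`aggregate_daily()` turns fixed-cadence records (default 10 min, the
stations' logging interval) into the daily inputs:

* `t_max`, `rh_min`, `wind_max`, `precip_total` — the extremes/total of
  the day's records;
* `humus_vwc` — the daily mean of the 10 cm soil probe. The probe sits in
  the humus layer, so its reading is used directly; the daily mean was
  chosen over an instantaneous value to damp the within-day infiltration
  spike. The 40 cm probe is carried through and reported but never enters
  the grade;
* `dry_run`, `wet_run` — consecutive days, ending today, below/at-or-above
  the rain-day threshold (default 0.1 mm/day, configurable — the standard
  never defines "a day without precipitation"). Exactly one of the two is
  positive each day.

Days are delimited at station-local midnight (`aggregation_config(tz=)`).
Gaps of at most 30 minutes — the longest outage observed in the field
deployments the defaults are modelled on — are bridged by linear
interpolation of the continuous channels; missing precipitation intervals
in such gaps are treated as rain-free. Longer gaps leave the missing
stretch out of the statistics and flag the day; flagged days are still
scored, carrying the flag as a quality marker. A day with coverage below
80% raises a typed condition that carries the partial summary, and a
wholly missing day conservatively resets both run counters. Ingestion is
idempotent: duplicated rows and arbitrary row order do not change any
summary.

The run counter fed into $Y'_C$ is, by default, the dry run. The source
texts around this index are contradictory — the assessment-index list
calls C "consecutive days without precipitation" while the fitted $X_C$
values behave as precipitation amounts in mm, and $t$ is described as a
count of *rain* days even though $+5t$ increases fire danger. We
implement the printed arithmetic: $X_C$ is the day's precipitation in mm,
and $t$ counts consecutive rain-free days (switchable to the wet run via
`assess_series(c_run_counter = "wet")`). The $5(t-1)$ branch is negative
on a heavy-rain day ($t = 0$); clamping at zero is this package's
decision, made so that heavy rain cannot push the composite down through
a negative precipitation score.

## The synthetic station

`generate_weather()` emulates a mid-latitude forest station in the spring
fire season, at the stations' 10-minute cadence, 92 days by default (one
campaign season):

* temperature: mean 12 °C, diurnal cosine of amplitude 6 °C peaking at
  14:00, an AR(1) day-to-day synoptic offset (sd 2.5 °C) and AR(1)
  within-day noise (sd 1.5 °C);
* relative humidity: 0.55 base, anti-correlated with temperature at
  0.02 per °C, raised by 0.25 during rain intervals, clipped to [0, 1];
* wind: i.i.d. Weibull (shape 2, scale 3 m/s) per interval, with the
  anemometer's 0.3 m/s starting threshold and 60 m/s cap;
* rain occurrence: a daily two-state Markov chain
  ($p_{ww} = 0.5$, $p_{wd} = 0.15$, i.e. rain roughly one day in five);
  a wet day's amount is exponential with mean 5 mm, spread over one
  contiguous random event window of 30 min–4 h;
* soil: the 10 cm layer gains 0.01 VWC per mm of rain in the interval it
  falls and relaxes toward a dry floor (0.08 VWC) at 5% of its excess per
  day — a fast rise and slow decay; the 40 cm layer relaxes toward the
  10 cm layer at 10% per day, so a brief light shower barely moves it.

All randomness derives from one seed through named substreams (weather,
channel), so the channel can be re-seeded without disturbing the weather.
Parameter recovery (`recover_parameters()`) closes the loop: on a
2000-day simulation the wet-day frequency and mean wet-day rain come back
within their Monte-Carlo intervals.

What the generator does *not* emulate: frontal passages and seasonal
trends, humidity saturation physics, wind gust autocorrelation, snow,
evapotranspiration, or any specific site's series. Passing tests on
synthetic weather therefore demonstrate that the pipeline computes its
defined quantities correctly and responds to rain and drought in the
documented direction — not that grades at any real site are accurate.

## Telemetry frames

Stations in regions without cell coverage send each observation as one
72-byte satellite short message. Only the size is an external constraint;
the layout (version 1) is this package's own and is documented
byte-by-byte in `R/frames.R`: magic and version (3 bytes), station id
(uint16), POSIX timestamp (uint32), six channels as big-endian
fixed-point integers (temperature 0.01 °C steps, humidity and soil VWC
10^-4 steps, wind 0.01 m/s, precipitation 0.01 mm), 49 reserved bytes for
the stations' remaining sensor block, and a 16-bit checksum.
`transmit()` is a Bernoulli erasure channel (no latency or reordering):
each frame is independently delivered with the configured probability,
defaulting to 0.9857, the lower end of the delivery rates field
deployments of such links report.

## Problem sizes and numerical choices

The bundled fits involve 6–9 points each and complete in well under a
second. The test suite exercises the pipeline on simulated series of 1–92
days for behaviour and 2000 days for Monte-Carlo recovery; those sizes
give binomial half-widths of about 0.026 on the wet-day frequency, tight
enough to catch an off-by-one in the rain chain while keeping a test run
interactive. Grade classification rounds half-up before applying the
integer thresholds, preserving the published table verbatim; composite
totals below zero (possible when the soil correction dominates a calm wet
day) are Grade I. Humidity is a fraction everywhere inside the package —
the humidity curve's coefficients are only meaningful for fractional
input — and percent appears exclusively in the CSV dialect.

## Limitations

* The operational reference coefficients and the refitted ones disagree
  (above); the package defaults to the reference set for continuity with
  operational practice, and `assess` on the command line exposes
  `--params refit` for the least-squares set.
* The original stepwise standard is not reproduced (its interval
  boundaries are not part of the bundled tables), so no step-vs-smoothed
  comparison is offered.
* The phenology calendar defaults (fire season 1 Mar–15 Jun and
  15 Sep–30 Nov, core 15 Mar–31 May) are a northern-China spring/autumn
  pattern chosen by this package; any operational deployment should set
  its own calendar.
* Quality control stops at sensor-range checks and the gap policy; there
  is no drift or calibration model.
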