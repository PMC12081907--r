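# opiwatch

Surveillance of opioid discussion in social-media comment streams,
validated against official mortality and laboratory benchmarks.

Official signals about the opioid epidemic are slow: provisional overdose
death counts are published with a delay of about six months, and
forensic-laboratory drug reports appear semi-annually. Drug discussion in
public comment streams is observable within days. `opiwatch` is an R
package plus a scripted analysis that (i) mines opioid mentions from a
comment stream with a class-annotated lexicon, (ii) geolocates users into
a cohort via location-community membership, (iii) computes normalized
trailing comment rates and benchmark rates on aligned calendars, (iv)
quantifies lead/lag co-movement between the two with cross-correlation
under stationarity testing, and (v) measures the forecasting value of the
near-real-time comment signal added to the lag-delayed official series.
A synthetic-data generator reproduces the joint latent structure the
analysis assumes, so every stage is tested against known ground truth.

## The statistics at the core

**Normalized mention rate.** For drug category *c*, geography *g*, month
*m*:

    rate(c, g, m) = [unique cohort comments mentioning c] /
                    [all cohort comments] × 10,000

with a right-aligned trailing 12-month variant (month *m* sums *m−11…m*
in numerator and denominator). Benchmark rates divide death or report
counts by population (×10,000 or ×100,000).

**Lead/lag cross-correlation.** For offsets k ∈ [−L, L], the Pearson
correlation between the comment rate at *t* and the benchmark at *t + k*;
positive k means the benchmark trails. The detrended variant
first-differences both series, requires each to pass an augmented
Dickey–Fuller test (drift regression, AIC lag selection), escalates to
second differences if needed, and reports no correlation when
stationarity cannot be achieved.

**Rolling-origin ARIMA with an exogenous signal.** At each origin month
*t* the model sees the benchmark only up to *t − 6* (publication delay)
and, in the augmented variant, the comment rate up to *t − 1*; an ARIMA
(order AIC-selected once, coefficients refit per origin) is iterated
forward to predict month *t*. Paired absolute errors of the two models
are compared with a two-sided Wilcoxon signed-rank test whose null
distribution is computed exactly (rank generating-function convolution,
valid under ties) for n ≤ 25.

## Worked example

A synthetic study: 2,000 users over 48 months, mortality trailing the
comment signal by 5 months, and a ×2 non-drug "discourse shock" during
2018 (the final study year).

```r
library(opiwatch)

cfg <- sim_config(n_users = 2000, n_months = 48, start_month = "2015-01",
                  benchmark_lag_months = 5L,
                  mention_base_rate = 150, mention_coupling = 2,
                  mortality_coupling = 2, comments_per_user_month = 15,
                  latent_process = list(type = "random_walk", init = 1,
                                        drift = 0.01, sd = 0.2),
                  shock_window = list(start = "2018-01", end = "2018-12",
                                      multiplier = 2),
                  seed = 20260101)
sim    <- simulate_comment_stream(cfg)
bench  <- simulate_benchmarks(cfg, sim$truth)
lex    <- default_lexicon()
cohort <- build_cohort(sim$comments, default_location_map())
men    <- detect_mentions(sim$comments, lex)

reddit <- comment_rate_series(men, sim$comments, cohort, lex,
                              category = "all_opioids")
mort   <- benchmark_rate_series(bench$mortality, NULL, 1e4, "national")

cross_correlate(reddit, mort, max_lag = 7,
                exclude = c("2018-01", "2018-12"))
detrend_and_correlate(reddit, mort, max_lag = 7,
                      exclude = c("2018-01", "2018-12"))
```

```
Lead/lag cross-correlation (monthly)
  best lag: +5 (r = 0.914)
Lead/lag cross-correlation (monthly)
  differencing order: 1 | stationarity achieved: TRUE
  ADF p-values: a=0.01, b=0.01
  best lag: +5 (r = 0.832)
```

The configured 5-month benchmark delay is recovered both raw and after
detrending (the shock year is excluded from the comparison, as
pandemic-distorted years are in real-data analyses). The forecasting
experiment in the co-moving regime (`analysis/05_forecast.R`) prints:

```
-- stable discourse (no shock) --
MAE benchmark-only: 0.5105; with exogenous comment rate: 0.2985 (per 10,000)
signed-rank on paired absolute errors: V = 788, p = 0.0001461
-- 2x discourse shock inside evaluation window --
MAE benchmark-only: 0.5105; with exogenous comment rate: 0.5949 (per 10,000)
signed-rank on paired absolute errors: V = 538, p = 0.4361
```

Read: under stable discourse the fresh comment signal cuts the one-month
prediction error of the delayed benchmark by ~40%; a systemic discourse
shock dilutes the normalized mention rate (the denominator doubles while
the drug process is unchanged) and erases that advantage — the signature
failure mode of normalized social-media surveillance under events like a
pandemic.

## The analysis workflow

Numbered drivers under `analysis/` run the full study over the package
(`analysis/common.R` holds the shared configuration); each writes its
tables under `results/analysis/` and can be run standalone:

```sh
Rscript analysis/01_simulate.R        # stream + benchmark generation
Rscript analysis/02_mentions_cohort.R # mention mining, cohort, concordance
Rscript analysis/03_rates.R           # normalized rate series
Rscript analysis/04_alignment.R       # lead/lag cross-correlation
Rscript analysis/05_forecast.R        # rolling-origin ARIMA experiment
```

`run_pipeline()` orchestrates the same stages programmatically from one
configuration list (or YAML file) and writes a reproducible run manifest.

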