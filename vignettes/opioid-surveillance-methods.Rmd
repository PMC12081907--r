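---
title: "Methods: opioid-mention surveillance from comment streams"
author: "opiwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opioid-mention surveillance from comment streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The surveillance problem

Official measures of the opioid epidemic arrive late. Provisional overdose
mortality counts are published with a delay of roughly half a year, and
forensic-laboratory drug identification reports appear only semi-annually.
Public discussion of drugs on social media, by contrast, is observable
almost immediately. `opiwatch` implements a surveillance pipeline that asks,
end to end, whether the *rate of opioid mentions* in a comment stream —
normalized, geolocated, and aligned on a calendar — co-moves with official
mortality and laboratory series, and whether the near-real-time signal adds
predictive value on top of the delayed official one.

The pipeline has five analytic stages, each exposed as package functions
and each exercised by a synthetic-data generator with known ground truth:

1. **Mention detection** (`detect_mentions`): token-level matching of a
   class-annotated opioid lexicon against comment text.
2. **Cohort geolocation** (`build_cohort`): users are mapped to a state and
   census region through membership in location communities.
3. **Rate computation** (`comment_rate_series`, `benchmark_rate_series`):
   normalized mention rates per 10,000 cohort comments and benchmark rates
   per 10,000 (mortality) or 100,000 (laboratory reports) population, with
   right-aligned trailing 12-month windows.
4. **Lead/lag alignment** (`cross_correlate`, `detrend_and_correlate`):
   Pearson correlation at every offset in a symmetric window, raw and
   after differencing with augmented Dickey–Fuller stationarity checks.
5. **Forecasting** (`rolling_forecast`, `run_forecast_experiment`):
   rolling-origin ARIMA prediction of the benchmark from its own delayed
   history, with and without the fresh comment rate as an exogenous
   regressor, compared by an exact signed-rank test on paired absolute
   errors.

## Mention detection

Comment text is lowercased and split into tokens on runs of
non-alphanumeric characters. A mention is a whole-token match of a lexicon
surface term; multi-word terms (e.g. a two-word street name) match as
contiguous token sequences. Matching is longest-first, left to right, and
tokens consumed by a longer term are not re-used, so a term nested inside
another is never double-counted. There is no stemming and no edit-distance
matching: misspellings count only if they are explicit lexicon entries.
These rules are declared package conventions — token-level matching is the
operation the lexicon is built for, and the boundary rule is what prevents
a short term from firing inside a longer drug name
(`fent` inside `fentanyl`, `fentanyl` inside `sufentanil`).

The shipped lexicon is a curated fixture: the tracked opioids under their
canonical spellings plus a small illustrative set of brand names, street
names, and misspellings. Each canonical drug carries two class labels — a
mu-opioid receptor activity class (heroin / full, partial, mixed agonist /
antagonist) and a synthesis class (heroin / synthetic /
natural–semi-synthetic / other / excluded). Methadone is annotated
`excluded` in the synthesis taxonomy, following the mortality-reporting
convention, so it resolves under `all_opioids` and receptor-class queries
but never under a synthesis category. One taxonomic wrinkle: oxymorphone
belongs to the natural/semi-synthetic class definition, so it ships in the
lexicon even though it sits outside the most-discussed set; category
resolution works off the lexicon annotations and would otherwise silently
shrink the class.

A comment that names drugs from two categories counts once in each
category's comment tally; within one category it counts once no matter how
many of the category's drugs it names. The per-drug summary counts
*mention occurrences*, *unique comments*, and *unique users* separately,
which is why mentions ≥ comments ≥ (distinct users) holds for every drug.

## Cohort geolocation

Posting in a location community is used as a proxy for living there. A
user qualifies for the cohort when they have posted *at least once* in
*exactly one distinct* location community; repeat posts in the same
community keep the user, posts in a second community disqualify them as
ambiguous. Inclusion is agnostic to whether the user ever mentioned a
drug, and all of a qualifying user's comments — including those predating
the first location post — count toward rates, since rates aggregate whole
posting histories. The observation window for location evidence is a
parameter (`window`), defaulting to the full stream. States map onto the
four U.S. census regions, the taxonomy the laboratory benchmark reports
in.

The per-state cohort size can be checked against census population with
Kendall's Tau-b (`cohort_population_concordance`); the implementation is
`stats::cor(method = "kendall")` and the test suite verifies it against
exhaustive pair enumeration. In the synthetic data the generator assigns
home regions by regional population weight but picks the community
*uniformly within the region*, so state-level concordance is attenuated by
design; the region-level recovery (100% for single-community users on a
noise-free stream) is the sharper validity check.

## Normalized rates

The comment-side rate for category *c*, geography *g*, month *m* is

$$ r_{c,g,m} = \frac{\#\{\text{unique comments by cohort users in } g
\text{ mentioning } c \text{ in } m\}}
{\#\{\text{all comments by cohort users in } g \text{ in } m\}}
\times 10{,}000. $$

Normalizing by cohort *comments* rather than cohort *size* keeps inactive
users from diluting the measure. The trailing 12-month variant is
right-aligned — the entry for month *m* sums months *m−11…m* in both
numerator and denominator — and is only emitted once 12 months of history
exist. Months with no cohort comments contribute zero to both trailing
sums (with a warning) rather than invalidating the window. Semiannual
binning uses calendar halves (Jan–Jun, Jul–Dec), the laboratory reporting
convention. Benchmark rates divide counts by a fixed population
denominator (per 10,000 for deaths, per 100,000 for laboratory reports);
the trailing mortality variant sums counts over 12 months against the same
population, matching the provisional-mortality convention.

## Lead/lag cross-correlation

`cross_correlate(a, b, max_lag)` computes the Pearson correlation between
`a` shifted by every offset `k` in `[-max_lag, max_lag]` and `b` on their
calendar overlap. The sign convention is declared: **positive `k` means
the benchmark trails the comment series by `k` periods** (the comment
value at `t` pairs with the benchmark value at `t + k`). The best lag is
the offset maximizing |r|, with the signed r reported; ties break toward
the smallest |lag|, negative before positive. An exclusion window (e.g.
pandemic-distorted years) is applied by calendar period after alignment,
so the same months drop from both sides.

The detrended variant differences both series at order 1, tests each
differenced series with an augmented Dickey–Fuller test at α = 0.05,
escalates to order 2 if either fails, and *refuses to report a
correlation* when stationarity cannot be achieved — mirroring how
benchmark pairs that cannot be detrended are reported as such rather than
forced. Differencing a pure linear trend produces a constant, whose
correlation is undefined; this degenerate case is detected and reported
as a failure, not a number. A difference entry whose span touches an
excluded month is itself contaminated (it straddles a regime edge), so
the exclusion window is widened by the differencing order before pairs
are formed.

Because no unit-root test ships with the base distribution, the ADF test
is implemented in the package: the "drift" regression (constant, no
deterministic trend)

$$\Delta y_t = \alpha + \rho\, y_{t-1} + \sum_{i=1}^{k} \phi_i \Delta
y_{t-i} + \epsilon_t,$$

with the augmentation order `k` chosen by AIC over a common estimation
sample and the t-ratio of ρ referred to interpolated finite-sample
quantiles of the tau distribution for the drift case (p-values clamped to
[0.01, 0.99]). The statistic is verified in the test suite against an
independent reference implementation at fixed lag order. The drift
specification and α = 0.05 are package defaults; rate series have
non-zero levels, making the constant appropriate, and nothing in the
procedure depends on the trend variant.

A permutation band (`xcorr_permutation_band`) gives a null reference for
the maximum |r| over lags: one series is permuted, the maximum recomputed,
and the 95th percentile reported. No parametric confidence intervals on r
are attempted.

## Rolling-origin forecasting

The experiment mimics deployment. At each origin month `t` the model may
use benchmark values only up to `t − benchmark_lag` (default 6, the
publication delay) and, in the augmented variant, comment rates up to
`t − exog_lag` (default 1). An ARIMA (no seasonal terms) is fit on the
available target history — with the comment rate as an exogenous
regressor in the augmented model — and iterated forward to month `t`:
the gap is bridged by multi-step prediction, with observed exogenous
values supplied where available and the last available value held for the
remaining steps. Predictions are clipped at zero since rates are
non-negative. The first origin requires 24 months of observed target
history (two years), and the horizon is one month.

Order selection runs once, at the first origin: the differencing order d
comes from repeated ADF testing (difference until stationary, at most
d = 2), then (p, q) minimize AIC over the exhaustive grid p, q ≤ 3.
Coefficients are refit at every origin; full re-selection per origin is a
configuration flag (`reselect_each_origin`). An exhaustive small grid was
preferred over a stepwise search over a larger one: at monthly
surveillance lengths the grid is cheap, immune to stepwise path
dependence, and orders beyond (3, 2, 3) are not estimable with stability
anyway. When a fit fails to converge at an origin the model falls back to
a drift-only forecast for that origin and records the fallback.

Baseline and augmented absolute errors are paired by month and compared
two-sided with a Wilcoxon signed-rank test implemented in the package:
zero differences are dropped, |differences| are ranked with average ranks
for ties, and for n ≤ 25 the null distribution of the rank sum is built
exactly by convolving the rank generating function — equivalent to
enumerating all 2^n sign assignments and, unlike the textbook no-ties
tabulation, still exact under tied ranks. Beyond n = 25 a normal
approximation with continuity correction is used, with tie structure
entering through Var(V) = Σr²/4. The exact path is verified against
brute-force enumeration in the tests.

One structural point the synthetic experiments make explicit: the
exogenous signal's advantage is the *publication delay*, not clairvoyance.
When the benchmark co-moves with the comment signal at lag zero, comment
data at `t − 1` carries information about the benchmark at `t` that the
delayed benchmark history (ending at `t − 6`) cannot, and the augmented
model wins decisively. When the benchmark intrinsically trails the latent
process by several months, the delayed history already contains most of
the predictable signal and a contemporaneous regressor adds little. The
forecasting analysis therefore targets the co-moving regime, which is
also where the strongest raw correlations are observed.

## The synthetic-data generator

The generator encodes the causal structure the analysis assumes — a
single latent "drug-use intensity" per region driving both channels — so
that every downstream stage can be checked against known truth:

* **Latent intensity**: per region, either a random walk with drift
  (default: init 1, drift 0.01/month, innovation s.d. 0.05; the analysis
  scripts use 0.2 for a signal-to-noise ratio near 3) or a piecewise
  linear path with changepoints. Values are clamped at zero. The series
  is generated with |lag| months of padding from independent substreams,
  so the visible window is invariant to the padding and the shifted
  benchmark channel never needs edge-holding.
* **Users**: home region sampled by regional population weight;
  with probability `p_single_location` (default 0.6) the user posts in
  exactly one location community of their home region, with
  `p_multi_location` (0.1) in two or three communities, otherwise in
  none. One guaranteed location post per membership makes the posting
  profile a construction rather than a probabilistic hope.
* **Comments**: per user-month counts are negative binomial
  (mean 10, dispersion 1.0) — overdispersion is realistic and stresses
  the normalization. Each base comment carries a drug mention with
  probability `mention_base_rate/10^4 × (1 + mention_coupling ×
  intensity)`, the surface form drawn uniformly from the lexicon and
  embedded in templated filler text whose vocabulary is disjoint from the
  lexicon. Comment text is templated, not natural language: token-level
  matching is all the detector needs.
* **Benchmarks**: monthly deaths are Poisson with rate
  `population/10^4 × mortality_base_rate × (1 + mortality_coupling ×
  intensity)` where the intensity is shifted by `benchmark_lag_months`
  (positive = benchmark trails); semiannual laboratory counts aggregate
  the same shifted signal over calendar halves at a per-100,000 base
  rate. Setting the noise switches to `"none"` yields expected counts
  exactly, which is how the noise-free recovery properties are tested.
* **Discourse shock**: over a configurable window, *non-drug* comment
  volume is multiplied (default scenario: ×2 for twelve months). The
  drug-mention process is untouched, so the normalized mention rate is
  diluted by the denominator while mortality is unaffected — the
  qualitative signature of a pandemic-style discourse shift, and the
  scenario in which the exogenous forecast signal becomes misleading.
* **Seeding**: one master seed spawns labelled substreams per component,
  so adding a component never perturbs the draws of another, and a fixed
  (seed, config) pair reproduces every record byte for byte.

Population weights are fixed over the horizon (a stated simplification;
the real normalization re-anchors to census estimates per year). The
noise family of real per-user comment counts is not documented anywhere;
negative binomial is this package's choice. An aggregate month-level
generator (`simulate_signal_pair`) draws the same latent/Poisson
structure without per-comment text, making replicate-heavy experiments
(hundreds of lag-recovery runs) affordable; the two paths are
consistency-checked in the tests.

What passing synthetic tests do **not** show: robustness to natural
language (sarcasm, negation, news events), to users who move, to
demographic skew of the platform, or to secular changes in how drugs are
named. The generator makes the *statistical* plumbing falsifiable, not
the sociolinguistics.

## Problem sizes and numerical choices

The analysis scripts run a 2,000-user, 48-month stream (~1.8 M comments)
with a +5-month benchmark lag and a 2× shock year; the forecasting script
uses 72 months in the co-moving regime. The test suite uses smaller
streams (hundreds of users) plus replicate batteries: 200 replicates per
configured lag for detrended lag recovery, 200 replicates each for the
exogenous-power and null-size properties of the forecast comparison, and
a 500-month AR(1) series whose one-step mean absolute error is checked
against the analytic optimum σ√(2/π). Deterministic fits use fixed
optimizer settings; rate identities are exact to 1e-12 relative
tolerance; correlation and signed-rank values are checked against
brute-force oracles at machine precision.

Known numerical edges: ARIMA maximum likelihood degenerates when the
residual variance is exactly zero (an identically-satisfied exogenous
identity), so such constructions are tested with infinitesimal jitter;
ADF p-values are table interpolations clamped to [0.01, 0.99], not
continuous tail approximations; and the exact signed-rank distribution
doubles ranks to keep tied (half-integer) average ranks on an integer
lattice.

## Limitations

The package consumes a lexicon; it does not learn one. It performs no
context classification — a mention is a mention, whether reportage,
lived experience, or harm-reduction advice. Geolocation by community
membership assigns at most one home location per user, for the whole
observation period. State-level analyses are supported by the rate
machinery but the synthetic state-assignment is deliberately coarse, and
no claim is made about state coverage. Benchmark ingestion expects
pre-tabulated counts with population denominators; fetching or parsing
any upstream data source is out of scope.
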