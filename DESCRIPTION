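Package: opiwatch
Title: Social-Media Opioid-Mention Surveillance Against Mortality and
    Laboratory Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for lexicon-based surveillance of opioid discussion in
    social-media comment streams. Detects drug mentions with a
    class-annotated opioid lexicon, builds a geolocated user cohort from
    location-community membership, computes normalized trailing comment
    rates and benchmark mortality/laboratory rates on aligned calendars,
    quantifies lead/lag co-movement between the two via cross-correlation
    with augmented Dickey-Fuller stationarity testing and differencing,
    and evaluates the forecasting value of near-real-time comment rates
    added to lag-delayed official mortality data through rolling-origin
    ARIMA experiments with paired signed-rank error comparison. A
    synthetic-data generator produces comment streams and benchmark
    series with the joint latent structure the analysis assumes, so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
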