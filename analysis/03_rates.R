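#!/usr/bin/env Rscript
# Normalized rate series: monthly and trailing-12-month comment rates per
# drug category for the cohort, and population-normalized benchmark rates.

source("analysis/common.R")

cfg <- study_config()
sim <- simulate_comment_stream(cfg)
bench <- simulate_benchmarks(cfg, sim$truth)
lexicon <- default_lexicon()
cohort <- build_cohort(sim$comments, default_location_map())
mentions <- detect_mentions(sim$comments, lexicon)

for (cat_ in c("all_opioids", "synthetic", "heroin")) {
  for (win in c("none", "trailing_12m")) {
    rs <- comment_rate_series(mentions, sim$comments, cohort, lexicon,
                              category = cat_, geography = "national",
                              window = win)
    f <- sprintf("comment_rates_%s_%s.csv", cat_, win)
    write_rate_series_csv(rs, res_path(f))
  }
  say("category %-22s monthly mean rate %.1f per 10,000 comments", cat_,
      mean(read_rate_series_csv(
        res_path(sprintf("comment_rates_%s_none.csv", cat_)))$rate))
}

mort <- benchmark_rate_series(bench$mortality, populations = NULL,
                              scale = 1e4, geography = "national",
                              granularity = "monthly")
write_rate_series_csv(mort, res_path("mortality_rates_national.csv"))
lab <- benchmark_rate_series(bench$lab, populations = NULL, scale = 1e5,
                             geography = "national",
                             granularity = "semiannual")
write_rate_series_csv(lab, res_path("lab_rates_national.csv"))
say("mortality: %d monthly rates, mean %.2f per 10,000", nrow(mort),
    mean(mort$rate))
say("laboratory reports: %d semiannual rates, mean %.1f per 100,000",
    nrow(lab), mean(lab$rate))
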