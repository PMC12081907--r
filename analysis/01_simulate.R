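#!/usr/bin/env Rscript
# Generate the synthetic study data: a comment stream whose drug-mention
# rate tracks a latent regional intensity, plus mortality and laboratory
# benchmark series driven by the same intensity delayed by 5 months, with
# a 2x non-drug discourse shock during 2018.

source("analysis/common.R")

cfg <- study_config()
sim <- simulate_comment_stream(cfg)
bench <- simulate_benchmarks(cfg, sim$truth)

# the raw stream is bulky scratch material; only summary tables are kept
dir.create("scratch", showWarnings = FALSE)
write_comments_jsonl(sim$comments, "scratch/comments.jsonl")
write.csv(bench$mortality, res_path("benchmarks_monthly.csv"),
          row.names = FALSE)
write.csv(bench$lab, res_path("benchmarks_semiannual.csv"),
          row.names = FALSE)
write.csv(sim$truth$users, res_path("users_truth.csv"), row.names = FALSE)
jsonlite::write_json(list(true_lag = sim$truth$true_lag,
                          months = sim$truth$months),
                     res_path("truth.json"), auto_unbox = TRUE)

say("simulated %d comments from %d users over %d months",
    nrow(sim$comments), cfg$n_users, cfg$n_months)
say("benchmark channels trail the comment signal by %d months",
    sim$truth$true_lag)
say("national mortality rate spans %.2f-%.2f per 10,000",
    min(bench$mortality$rate[bench$mortality$geography == "national"]),
    max(bench$mortality$rate[bench$mortality$geography == "national"]))
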