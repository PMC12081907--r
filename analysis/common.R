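# Shared settings for the analysis scripts. Every script can be run from
# the repository root with `Rscript analysis/0X_*.R`; outputs accumulate
# under results/analysis/.

suppressPackageStartupMessages(library(opiwatch))

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

MASTER_SEED <- 20260101L

# Study conditions for the synthetic cohort: a benchmark that trails the
# comment signal by 5 months, a 2x discourse shock over the final study
# year, and a latent intensity drifting upward with random-walk noise.
study_config <- function() {
  sim_config(
    n_users = 2000,
    n_months = 48,
    start_month = "2015-01",
    benchmark_lag_months = 5L,
    mention_base_rate = 150,
    mention_coupling = 2,
    mortality_base_rate = 1.5,
    mortality_coupling = 2,
    comments_per_user_month = 15,
    p_single_location = 0.6,
    p_multi_location = 0.1,
    latent_process = list(type = "random_walk", init = 1,
                          drift = 0.01, sd = 0.2),
    shock_window = list(start = "2018-01", end = "2018-12",
                        multiplier = 2),
    seed = MASTER_SEED)
}

res_path <- function(...) file.path(RESULTS_DIR, ...)
say <- function(...) cat(sprintf(...), "\n")
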