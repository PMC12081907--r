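#!/usr/bin/env Rscript
# Detect lexicon drug mentions in the simulated stream, tabulate them per
# drug and per class, and build the location cohort. Regenerates the
# stream from the same seed, so it can run standalone.

source("analysis/common.R")

cfg <- study_config()
sim <- simulate_comment_stream(cfg)
lexicon <- default_lexicon()
locmap <- default_location_map()

mentions <- detect_mentions(sim$comments, lexicon)
dir.create("scratch", showWarnings = FALSE)
write.csv(mentions, "scratch/mentions.csv", row.names = FALSE)

summ <- summarize_mentions(mentions, lexicon)
write.csv(summ$by_drug, res_path("mention_summary_by_drug.csv"),
          row.names = FALSE)
write.csv(summ$by_receptor_class,
          res_path("mention_summary_by_receptor_class.csv"),
          row.names = FALSE)
say("detected %d mention occurrences in %d distinct comments",
    sum(mentions$n_occurrences), length(unique(mentions$comment_id)))
say("top drugs by mentions:")
print(head(summ$by_drug, 5))

cohort <- build_cohort(sim$comments, locmap)
write.csv(cohort, res_path("cohort.csv"), row.names = FALSE)
excl <- attr(cohort, "exclusions")
say("cohort: %d users assigned (%d multi-location excluded, %d without location evidence)",
    nrow(cohort), excl$n_multi_location, excl$n_no_location)

mrg <- merge(cohort, sim$truth$users, by = "user_id")
say("home-region recovery among single-location users: %.1f%%",
    100 * mean(mrg$region == mrg$home_region))

conc <- cohort_population_concordance(cohort, default_state_populations())
say("Kendall tau between per-state cohort size and census population: %.3f (%d states)",
    conc$tau, conc$n_states)
write.csv(conc$table, res_path("cohort_state_concordance.csv"),
          row.names = FALSE)
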