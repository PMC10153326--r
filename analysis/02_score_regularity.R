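#!/usr/bin/env Rscript
# Stage 2: score sleep regularity from the epoch series.
#
# Computes one SRI value per contiguous day pair, nightly onset/duration/WASO
# summaries, and the SD-based regularity metrics (SD of nightly duration and
# of onset time) used for comparison with the SRI.

suppressMessages(library(srisurv))
cfg <- read_run_config(file.path("analysis", "config.yaml"))

series <- read_epoch_series(file.path("results", "epoch_series.csv.gz"))
pairs <- cohort_day_pairs(series, cfg$metrics$min_pair_fraction)
nights <- lapply(series, night_summaries)
sds <- do.call(rbind, lapply(nights, function(ns) {
  s <- regularity_sds(ns)
  data.frame(participant_id = ns$participant_id[1],
             duration_sd = s$duration_sd, onset_sd = s$onset_sd,
             sleep_duration = mean(ns$duration), waso = mean(ns$waso))
}))

write_cohort_table(pairs, file.path("results", "day_pairs.csv"))
write_cohort_table(do.call(rbind, nights), file.path("results", "night_summaries.csv"))
write_cohort_table(sds, file.path("results", "regularity_sds.csv"))

excl <- attr(pairs, "excluded")
cat(sprintf("%d day-pair SRI values from %d participants (%.1f%% valid pairs).\n",
            sum(pairs$valid), length(series), 100 * mean(pairs$valid)))
cat(sprintf("%d participant(s) with fewer than 2 valid pairs flagged for exclusion.\n",
            length(excl)))
cat(sprintf("Mean nightly duration %.2f h, mean WASO %.2f h.\n",
            mean(sds$sleep_duration), mean(sds$waso)))
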