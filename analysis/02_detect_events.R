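#!/usr/bin/env Rscript
# Saccade detection and trial exclusions.  Velocity-threshold detection
# (median-based elliptic threshold on smoothed 2D eye velocity), first
# interceptive saccade per trial, SVC, open-loop pursuit window, and the
# sequential exclusion rules (gaze quality; latency outside 100-600 ms;
# amplitude outside 3-20 dva; duration > 100 ms; pursuit speed > 60 dva/s).

library(driftgaze)

trials <- read.csv("results/trials.csv")
gaze <- readRDS("results/gaze.rds")
cfg <- pipeline_config()

feats <- extract_trial_features(trials, gaze, cfg)
full <- merge(trials, feats[, setdiff(names(feats), "participant")],
              by = "trial_id", sort = FALSE)
excl <- apply_exclusions(full)

write.csv(feats, "results/saccades.csv", row.names = FALSE)
write.csv(excl$report, "results/exclusions.csv", row.names = FALSE)
write.csv(excl$kept, "results/kept_trials.csv", row.names = FALSE)

cat("exclusion stages (percent of survivors of the previous stage):\n")
print(excl$counts, row.names = FALSE)
kept <- excl$kept
cat(sprintf("kept %d of %d trials; mean latency %.0f ms (control %.0f, dd %.0f)\n",
            nrow(kept), nrow(full), mean(kept$latency_ms),
            mean(kept$latency_ms[kept$condition == "control"]),
            mean(kept$latency_ms[kept$condition == "dd"])))
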