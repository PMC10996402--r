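#!/usr/bin/env Rscript
# Why is the saccadic bias smaller than the pursuit bias?  Two-segment
# extrapolation account: the saccade target is extrapolated along the early
# (biased) pursuit direction for only part of the onset-to-landing interval.
# Solves for that extrapolation interval, first with the published group
# means as inputs, then with this cohort's own recovered biases.

library(driftgaze)

# published group means: saccade bias 10.98 deg, pursuit bias 25.25 deg,
# 230 ms mean double-drift latency + 36 ms expected duration
pub <- estimate_extrapolation_interval(10.98, 25.25, 230 + 36, 12)
print(pub)
pub230 <- estimate_extrapolation_interval(10.98, 25.25, 230, 12)
cat(sprintf("latency-only convention (230 ms total): t_e = %.1f ms\n",
            pub230$t_e))

summ <- jsonlite::read_json("results/summary.json", simplifyVector = TRUE)
g <- summ$group_bias
bs <- g$mean_bias_deg[g$modality == "saccade"]
bp <- g$mean_bias_deg[g$modality == "pursuit"]
kept <- read.csv("results/kept_trials.csv")
tt <- mean(kept$latency_ms[kept$condition == "dd"]) +
  mean(kept$duration_ms[kept$condition == "dd"])
own <- estimate_extrapolation_interval(bs, bp, tt, 12)
cat(sprintf("this cohort (saccade %.2f deg, pursuit %.2f deg, %.0f ms): t_e = %.1f ms\n",
            bs, bp, tt, own$t_e))
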