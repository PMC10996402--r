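#!/usr/bin/env Rscript
# Open-loop post-saccadic pursuit: speed and gain by condition.  The pursuit
# window (20-100 ms after saccade landing) is measured on FIR low-pass
# filtered traces; speed is the norm of the window-averaged velocity.

library(driftgaze)

kept <- read.csv("results/kept_trials.csv")
purs <- kept[, c("trial_id", "participant", "condition", "pursuit_dir_deg",
                 "pursuit_speed_dva_s", "pursuit_gain", "presacc_flag",
                 "presacc_dir_deg")]
write.csv(purs, "results/pursuit.csv", row.names = FALSE)

by_part <- aggregate(pursuit_speed_dva_s ~ participant + condition, purs,
                     mean)
speed_c <- by_part$pursuit_speed_dva_s[by_part$condition == "control"]
speed_d <- by_part$pursuit_speed_dva_s[by_part$condition == "dd"]
gain <- aggregate(pursuit_gain ~ participant, purs, mean)$pursuit_gain

cat(sprintf("pursuit speed: %.2f dva/s (SD %.2f) control, %.2f (SD %.2f) double-drift\n",
            mean(speed_c), sd(speed_c), mean(speed_d), sd(speed_d)))
cat(sprintf("pursuit gain: %.3f (SD %.3f) of the 12 dva/s target\n",
            mean(gain), sd(gain)))
cat(sprintf("presaccadic pursuit above baseline threshold on %.1f%% of trials\n",
            100 * mean(purs$presacc_flag, na.rm = TRUE)))
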