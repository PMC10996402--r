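#!/usr/bin/env Rscript
# Calibrate the saccadic direction readout on control trials: for each
# participant and motion direction, evaluate the 32-model circular-circular
# regression family by leave-one-out cross-validation and keep the best
# model.  Reports the cross-validated angular error of the selected models
# against the raw SVC direction error on the same trials.

library(driftgaze)

kept <- read.csv("results/kept_trials.csv")
models <- fit_calibrations(kept)

ctrl <- kept[kept$condition == "control", ]
raw_err <- mean(abs(ang_diff(ctrl$svc_angle_deg, ctrl$phys_dir_deg)))
cv <- vapply(models, function(m) m$cv_error, numeric(1))

calib <- lapply(models, function(m) list(
  spec = as.list(m$spec), cv_error_deg = m$cv_error, n_train = m$n_train,
  r2_cos = m$r2_cos, r2_sin = m$r2_sin,
  coef = list(names = rownames(m$coef), cos = unname(m$coef[, 1]),
              sin = unname(m$coef[, 2]))))
jsonlite::write_json(calib, "results/calibration.json", auto_unbox = TRUE,
                     digits = NA)
saveRDS(models, "results/models.rds")

cat(sprintf("mean LOO-CV error of selected models: %.2f deg\n", mean(cv)))
cat(sprintf("raw SVC direction error on the same control trials: %.2f deg\n",
            raw_err))
cat(sprintf("error reduction: %.0f%%\n", 100 * (1 - mean(cv) / raw_err)))
cat(sprintf("mean R2: %.3f (cos), %.3f (sin)\n",
            mean(vapply(models, `[[`, 0, "r2_cos")),
            mean(vapply(models, `[[`, 0, "r2_sin"))))
cat("selected specifications:\n")
for (k in names(models)) {
  s <- models[[k]]$spec
  cat(sprintf("  %-10s svc deg %d, sacdir deg %d%s%s%s (cv %.2f deg, n %d)\n",
              k, s$svc_degree, s$sacdir_degree,
              if (s$sacdir_interaction) " x interaction" else "",
              if (s$latency_interaction) " + latency" else "",
              if (s$amplitude_interaction) " + amplitude" else "",
              models[[k]]$cv_error, models[[k]]$n_train))
}
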