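# Orchestration: simulate -> detect -> pursuit -> calibrate -> bias tables ->
# summary.  Every stage is an exported function over plain data frames so the
# analysis scripts, the tests, and external data can all drive it.

#' Pipeline configuration
#'
#' @param simulation A [sim_config()] (used when no data are supplied).
#' @param detection A [detection_config()].
#' @param pursuit_window Post-saccadic window relative to saccade offset, ms.
#'   The default follows the 20-100 ms analysis interval; `c(20, 80)` is the
#'   preset matching the alternative 80-ms endpoint.
#' @param n_boot,ci_level Bootstrap settings for per-participant CIs.
#' @param seed Master seed for bootstrap resampling.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            detection = detection_config(),
                            pursuit_window = c(20, 100),
                            n_boot = 2000, ci_level = 0.95,
                            seed = 1) {
  structure(list(simulation = simulation, detection = detection,
                 pursuit_window = pursuit_window, n_boot = n_boot,
                 ci_level = ci_level, seed = seed),
            class = "pipeline_config")
}

#' Extract saccade and pursuit features for every trial
#'
#' Runs saccade detection, selects the first interceptive saccade, filters
#' the trace, and computes the post-saccadic pursuit estimate, the
#' presaccadic screen, the SVC, and the gaze-quality flag, one row per trial.
#'
#' @param trials Trial table (see [simulate_experiment()] for the schema).
#' @param gaze Long gaze table keyed by `trial_id`.
#' @param cfg A [pipeline_config()].
#' @return Data frame: one row per trial with saccade, SVC, pursuit and
#'   quality columns (`NA` where a stage failed).
#' @export
extract_trial_features <- function(trials, gaze, cfg = pipeline_config()) {
  gz <- split(gaze[, c("t_ms", "x", "y")], gaze$trial_id)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- gz[[tr$trial_id]]
    row <- data.frame(
      trial_id = tr$trial_id, participant = tr$participant,
      bad_gaze = TRUE, latency_ms = NA_real_, onset_ms = NA_real_,
      offset_ms = NA_real_, start_x = NA_real_, start_y = NA_real_,
      end_x = NA_real_, end_y = NA_real_, amplitude_dva = NA_real_,
      duration_ms = NA_real_, peak_vel_dva_s = NA_real_,
      sacc_dir_deg = NA_real_, svc_angle_deg = NA_real_,
      svc_speed_dva_s = NA_real_, pursuit_dir_deg = NA_real_,
      pursuit_speed_dva_s = NA_real_, pursuit_gain = NA_real_,
      presacc_flag = NA, presacc_dir_deg = NA_real_)
    feats <- tryCatch({
      ev <- detect_saccades(g, cfg$detection)
      sac <- first_interceptive_saccade(ev, tr$onset_t_ms)
      bad <- preonset_violation(g, ev, tr$onset_t_ms)
      svc <- compute_svc(c(tr$onset_x_dva, tr$onset_y_dva),
                         c(sac$end_x, sac$end_y),
                         tr$onset_t_ms, sac$offset_t)
      gf <- lowpass_filter(g)
      purs <- tryCatch(
        pursuit_estimate(gf, sac, tr$envelope_speed_dva_s,
                         cfg$pursuit_window),
        error = function(e) NULL)
      pre <- tryCatch(presaccadic_pursuit(gf, sac, tr$onset_t_ms),
                      error = function(e) NULL)
      row$bad_gaze <- bad
      row$latency_ms <- sac$latency_ms
      row$onset_ms <- sac$onset_t; row$offset_ms <- sac$offset_t
      row$start_x <- sac$start_x; row$start_y <- sac$start_y
      row$end_x <- sac$end_x; row$end_y <- sac$end_y
      row$amplitude_dva <- sac$amplitude_dva
      row$duration_ms <- sac$duration_ms
      row$peak_vel_dva_s <- sac$peak_vel_dva_s
      row$sacc_dir_deg <- wrap_angle(rad2deg(atan2(sac$end_y - sac$start_y,
                                                   sac$end_x - sac$start_x)))
      row$svc_angle_deg <- svc$angle
      row$svc_speed_dva_s <- svc$magnitude
      if (!is.null(purs)) {
        row$pursuit_dir_deg <- purs$direction
        row$pursuit_speed_dva_s <- purs$speed
        row$pursuit_gain <- purs$gain
      }
      if (!is.null(pre)) {
        row$presacc_flag <- pre$above_threshold
        row$presacc_dir_deg <- pre$direction
      }
      row
    }, error = function(e) row)
    out[[i]] <- feats
  }
  do.call(rbind, out)
}

#' Fit per-participant, per-direction calibration models
#'
#' @param kept Trial table joined with features, control trials only.
#' @return Named list of `"calibration_model"` objects, keys
#'   `"<participant>.<motion_dir>"`.
#' @export
fit_calibrations <- function(kept) {
  ctrl <- kept[kept$condition == "control", , drop = FALSE]
  keys <- unique(paste(ctrl$participant, ctrl$motion_dir, sep = "."))
  models <- list()
  for (k in keys) {
    sub <- ctrl[paste(ctrl$participant, ctrl$motion_dir, sep = ".") == k, ]
    models[[k]] <- select_model(sub)
  }
  models
}

#' Bias rows for one analyzed trial
#'
#' For a double-drift trial that survived the exclusions, emits the
#' perception, pursuit, calibrated-saccade and raw-SVC direction biases
#' (positive = toward the internal drift).
#'
#' @param trial One row of the trial table joined with features.
#' @param model The participant-direction `"calibration_model"`.
#' @return Data frame with columns `trial_id`, `participant`, `modality`,
#'   `bias_deg`; zero rows for control trials.
#' @export
run_trial_analysis <- function(trial, model) {
  if (trial$condition != "dd") return(NULL)
  if (is.null(model)) stop("missing calibration model")
  pred <- predict_target_direction(model, trial)
  mods <- c("perception", "pursuit", "saccade", "raw_svc")
  resp <- c(trial$report_dir_deg, trial$pursuit_dir_deg, pred,
            trial$svc_angle_deg)
  ok <- !is.na(resp)
  data.frame(trial_id = trial$trial_id, participant = trial$participant,
             modality = mods[ok],
             bias_deg = direction_bias(resp[ok], trial$phys_dir_deg,
                                       trial$internal_sign))
}

#' Per-participant summary of direction biases
#'
#' Angular mean, circular SD and a bootstrap percentile CI per modality, and
#' the circular-circular correlations between modality pairs on common
#' trials.
#'
#' @param biases Bias rows of one participant ([run_trial_analysis()] form).
#' @param n_boot,level,seed Bootstrap settings.
#' @return List with `modality` (data frame) and `correlations` (data frame).
#' @export
summarize_participant <- function(biases, n_boot = 2000, level = 0.95,
                                  seed = 1) {
  mods <- sort(unique(biases$modality))
  md <- lapply(seq_along(mods), function(j) {
    b <- biases$bias_deg[biases$modality == mods[j]]
    ci <- bootstrap_ci(b, stat = function(v) as.numeric(angular_mean(v)),
                       n_boot = n_boot, level = level, seed = seed + j)
    data.frame(modality = mods[j], n = length(b),
               mean_bias_deg = as.numeric(angular_mean(b)),
               circ_sd_deg = circ_sd(b),
               ci_lower = ci$lower, ci_upper = ci$upper)
  })
  pairs <- utils::combn(setdiff(mods, "raw_svc"), 2)
  cors <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- biases[biases$modality == pairs[1, j], c("trial_id", "bias_deg")]
    b <- biases[biases$modality == pairs[2, j], c("trial_id", "bias_deg")]
    m <- merge(a, b, by = "trial_id")
    cc <- tryCatch(circ_corr(m$bias_deg.x, m$bias_deg.y),
                   error = function(e) list(r = NA_real_, z = NA_real_,
                                            n = nrow(m)))
    data.frame(pair = paste(pairs[1, j], pairs[2, j], sep = "-"),
               r = cc$r, z = cc$z, n = cc$n)
  })
  list(modality = do.call(rbind, md), correlations = do.call(rbind, cors))
}

#' Run the full analysis on a cohort
#'
#' simulate (optional) -> per-trial features -> sequential exclusions ->
#' per-participant calibration on control trials -> per-trial bias rows ->
#' per-participant and group summaries.
#'
#' @param trials,gaze Input tables; when `NULL`, a cohort is simulated from
#'   `cfg$simulation`.
#' @param cfg A [pipeline_config()].
#' @return List: `features`, `exclusions` (report + counts), `models`,
#'   `biases`, `pursuit` (per-trial pursuit/gain rows), `summary` (list with
#'   per-participant tables, group means, correlations, exclusion
#'   percentages).
#' @export
analyze_cohort <- function(trials = NULL, gaze = NULL,
                           cfg = pipeline_config()) {
  if (is.null(trials)) {
    message("simulating cohort: ", cfg$simulation$n_participants,
            " participants x ", cfg$simulation$n_trials, " trials")
    ds <- simulate_experiment(cfg$simulation)
    trials <- ds$trials; gaze <- ds$gaze
  }
  message("extracting features for ", nrow(trials), " trials")
  feats <- extract_trial_features(trials, gaze, cfg)
  full <- merge(trials, feats[, setdiff(names(feats), "participant")],
                by = "trial_id", sort = FALSE)
  excl <- apply_exclusions(full)
  message("exclusions: ", nrow(full) - nrow(excl$kept), " of ", nrow(full),
          " trials")
  kept <- excl$kept
  message("fitting calibration models (32-model LOO-CV per participant x ",
          "direction)")
  models <- fit_calibrations(kept)
  dd <- kept[kept$condition == "dd", , drop = FALSE]
  bias_rows <- vector("list", nrow(dd))
  for (i in seq_len(nrow(dd))) {
    key <- paste(dd$participant[i], dd$motion_dir[i], sep = ".")
    bias_rows[[i]] <- run_trial_analysis(dd[i, ], models[[key]])
  }
  biases <- do.call(rbind, bias_rows)
  if (is.null(biases) || nrow(biases) == 0)
    stop("no double-drift trials survived the exclusions")
  pursuit <- kept[, c("trial_id", "participant", "condition",
                      "pursuit_dir_deg", "pursuit_speed_dva_s",
                      "pursuit_gain", "presacc_flag", "presacc_dir_deg")]
  message("summarizing ", length(unique(biases$participant)),
          " participants")
  summary <- summarize_cohort(biases, pursuit, models, excl, cfg)
  list(features = feats, exclusions = excl, models = models,
       biases = biases, pursuit = pursuit, summary = summary)
}

# Group-level summary tables.
summarize_cohort <- function(biases, pursuit, models, excl, cfg) {
  parts <- sort(unique(biases$participant))
  per_part <- lapply(parts, function(p) {
    s <- summarize_participant(biases[biases$participant == p, ],
                               n_boot = cfg$n_boot, level = cfg$ci_level,
                               seed = cfg$seed + 1000 * p)
    s$modality$participant <- p
    s$correlations$participant <- p
    s
  })
  part_mod <- do.call(rbind, lapply(per_part, `[[`, "modality"))
  part_cor <- do.call(rbind, lapply(per_part, `[[`, "correlations"))
  group <- do.call(rbind, lapply(split(part_mod, part_mod$modality),
    function(d) data.frame(modality = d$modality[1],
                           mean_bias_deg = mean(d$mean_bias_deg),
                           sd_deg = stats::sd(d$mean_bias_deg),
                           n_participants = nrow(d))))
  gain_p <- vapply(split(pursuit$pursuit_gain, pursuit$participant),
                   mean, numeric(1), na.rm = TRUE)
  speed_p <- vapply(split(pursuit$pursuit_speed_dva_s, pursuit$participant),
                    mean, numeric(1), na.rm = TRUE)
  cors <- lapply(split(part_cor, part_cor$pair), function(d) {
    ok <- is.finite(d$r) & abs(d$r) < 1
    ci <- if (sum(ok) >= 2) pooled_fisher_ci(d$r[ok], cfg$ci_level)
          else list(mean = NA, lower = NA, upper = NA)
    data.frame(pair = d$pair[1], mean_r = ci$mean, ci_lower = ci$lower,
               ci_upper = ci$upper, n_participants = sum(ok))
  })
  cv <- vapply(models, function(m) m$cv_error, numeric(1))
  list(participant_modality = part_mod,
       participant_correlations = part_cor,
       group_bias = group,
       group_gain = list(mean = mean(gain_p), sd = stats::sd(gain_p),
                         per_participant = gain_p),
       group_pursuit_speed = list(mean = mean(speed_p),
                                  sd = stats::sd(speed_p)),
       correlations = do.call(rbind, cors),
       calibration_cv_error = list(mean = mean(cv), per_model = cv),
       exclusion_counts = excl$counts)
}

#' Run the pipeline and write the file bundle
#'
#' Writes `saccades.csv`, `exclusions.csv`, `pursuit.csv`, `biases.csv`,
#' `calibration.json` and `summary.json` to `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param trials,gaze Optional input tables (simulated otherwise).
#' @return Invisibly, the [analyze_cohort()] result.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = ".",
                         trials = NULL, gaze = NULL) {
  res <- analyze_cohort(trials, gaze, cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  sac_cols <- c("trial_id", "onset_ms", "offset_ms", "start_x", "start_y",
                "end_x", "end_y", "amplitude_dva", "duration_ms",
                "latency_ms", "peak_vel_dva_s")
  w(res$features[, sac_cols], "saccades.csv")
  w(res$exclusions$report, "exclusions.csv")
  w(res$pursuit, "pursuit.csv")
  w(res$biases, "biases.csv")
  calib <- lapply(res$models, function(m) list(
    spec = as.list(m$spec), cv_error_deg = m$cv_error,
    n_train = m$n_train, r2_cos = m$r2_cos, r2_sin = m$r2_sin,
    coef = list(names = rownames(m$coef), cos = unname(m$coef[, 1]),
                sin = unname(m$coef[, 2]))))
  jsonlite::write_json(calib, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message("wrote results to ", normalizePath(out_dir))
  invisible(res)
}

#' Adapter for the deposited experiment data
#'
#' Reads trial and gaze tables exported from the study's data deposit.  The
#' deposit's internal layout is not standardized, so this adapter expects the
#' user to export per-experiment CSVs with the package's column schema:
#' `trials.csv` (`trial_id`, `participant`, `condition` in `{control, dd}`,
#' `motion_dir`, `onset_x_dva`, `onset_y_dva`, `onset_t_ms`, `phys_dir_deg`,
#' `internal_sign`, `internal_speed_dva_s`, `envelope_speed_dva_s`,
#' `report_dir_deg`) and `gaze.csv` (`trial_id`, `t_ms`, `x_dva` or `x`,
#' `y_dva` or `y`; blank = missing sample).
#'
#' @param dir Directory containing `trials.csv` and `gaze.csv`.
#' @return List with `trials` and `gaze` in the pipeline's schema.
#' @export
read_osf_trials <- function(dir) {
  tf <- file.path(dir, "trials.csv"); gf <- file.path(dir, "gaze.csv")
  if (!file.exists(tf) || !file.exists(gf))
    stop("deposit not found: expected trials.csv and gaze.csv under ", dir,
         " (export them from the deposit; see ?read_osf_trials)")
  trials <- utils::read.csv(tf)
  gaze <- utils::read.csv(gf)
  names(gaze)[names(gaze) == "x_dva"] <- "x"
  names(gaze)[names(gaze) == "y_dva"] <- "y"
  need_t <- c("trial_id", "participant", "condition", "onset_x_dva",
              "onset_y_dva", "onset_t_ms", "phys_dir_deg", "internal_sign")
  miss <- setdiff(need_t, names(trials))
  if (length(miss))
    stop("trials.csv is missing columns: ", paste(miss, collapse = ", "))
  list(trials = trials, gaze = gaze)
}
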