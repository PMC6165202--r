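# End-to-end orchestration of the two studies: the eyes-closed/eyes-open
# alpha-SNR study and the mental-arithmetic vs light-cognitive
# classification study, over a set of simulated subjects with reproducible
# per-subject seeds and optional on-disk outputs plus a run manifest.

#' Build a run configuration
#'
#' Nested configuration for [run_ec_eo_study()] and [run_ma_lc_study()].
#' Every stochastic stage derives its seed from `seed`, so a configuration
#' fully determines the outputs.
#'
#' @param seed Master integer seed.
#' @param n_subjects Number of simulated subjects.
#' @param sim A `sim_config` (per-subject effect sizes are jittered around
#'   it by `subject_jitter`).
#' @param subject_jitter Log-scale SD of the per-subject multiplicative
#'   jitter applied to the condition effect sizes (between-subject spread).
#' @param rois ROIs analysed (any of `"frontal"`, `"central"`,
#'   `"occipital"`, `"ear"`, `"scalp"`).
#' @param preprocess,analysis,schedule Stage parameter lists; see Details.
#'
#' @details
#' `preprocess`: `lo`, `hi`, `order` (broadband filter), `target_fs`,
#' `threshold_task` / `threshold_rest` (peak-to-peak rejection, microvolts),
#' `epoch_window`, `baseline`.
#' `analysis`: `n_keep`, `k`, `reps`, `alpha_band`, `erders_step`.
#' `schedule`: `sessions`, `trials_per_cond`, `rest_range_s`, `ec_block_s`,
#' `ec_reps`.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, n_subjects = 5, sim = sim_config(),
                               subject_jitter = 0.08,
                               rois = c("frontal", "central", "occipital", "ear"),
                               preprocess = list(), analysis = list(),
                               schedule = list()) {
  pp <- utils::modifyList(
    list(lo = 1, hi = 50, order = 4, target_fs = 200,
         threshold_task = 126.67, threshold_rest = 196,
         epoch_window = c(-2, 10), baseline = c(-2, 0)),
    preprocess
  )
  an <- utils::modifyList(
    list(n_keep = 2, k = 10, reps = 10, alpha_band = c(8, 13),
         erders_step = 1),
    analysis
  )
  sc <- utils::modifyList(
    list(sessions = 5, trials_per_cond = 10, rest_range_s = c(10, 15),
         ec_block_s = 30, ec_reps = 6),
    schedule
  )
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects, sim = sim,
              subject_jitter = subject_jitter, rois = rois,
              preprocess = pp, analysis = an, schedule = sc)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!inherits(cfg$sim, "sim_config")) abort("sim must be a sim_config")
  if (cfg$n_subjects < 1) abort("n_subjects must be >= 1")
  bad <- setdiff(cfg$rois, c("frontal", "central", "occipital", "ear", "scalp"))
  if (length(bad)) abort(paste("unknown ROI(s):", paste(bad, collapse = ", ")))
  pp <- cfg$preprocess
  if (!(pp$lo > 0 && pp$lo < pp$hi)) abort("invalid filter band")
  if (pp$threshold_task <= 0 || pp$threshold_rest <= 0) abort("invalid threshold")
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("seed is required")
  invisible(cfg)
}

# Deterministic per-subject, per-purpose seed stream (kept below 2^31).
derive_seed <- function(seed, subject, purpose) {
  offset <- c(schedule = 1, sim = 2, blink = 3, cv = 4, jitter = 5)[[purpose]]
  as.integer((as.numeric(seed) * 499 + subject * 17 + offset) %% 2147483629)
}

# Per-subject effect sizes: multiplicative lognormal jitter on the excess
# gain, keeping ERS gains > 1 and the ERD attenuation in (0, 1].
subject_sim_config <- function(cfg, subject) {
  sim <- cfg$sim
  if (cfg$subject_jitter > 0) {
    withr::with_seed(derive_seed(cfg$seed, subject, "jitter"), {
      j <- function() exp(rnorm(1, 0, cfg$subject_jitter))
      sim$ec_alpha_gain <- 1 + (sim$ec_alpha_gain - 1) * j()
      sim$ma_alpha_ers <- 1 + (sim$ma_alpha_ers - 1) * j()
      sim$lc_alpha_gain <- 1 + (sim$lc_alpha_gain - 1) * j()
      sim$ma_beta_gamma_erd <- min(1, sim$ma_beta_gamma_erd^j())
    })
  }
  sim$seed <- derive_seed(cfg$seed, subject, "sim")
  sim
}

#' Simulate one subject's recording
#'
#' Generates the schedule and continuous EEG for one subject under a run
#' configuration, with per-subject seeds and (for the main paradigm)
#' per-subject effect-size jitter and injected blinks.
#'
#' @param config A `run_config`.
#' @param subject Subject index (1-based).
#' @param paradigm `"main"` (MA/LC trials) or `"ec_eo"` (resting blocks).
#' @return An `eeg_recording`.
#' @export
simulate_subject <- function(config, subject, paradigm = c("main", "ec_eo")) {
  paradigm <- match.arg(paradigm)
  validate_run_config(config)
  montage <- build_default_montage()
  sim <- subject_sim_config(config, subject)
  sc <- config$schedule
  if (paradigm == "ec_eo") {
    sch <- generate_ec_eo_schedule(sc$ec_block_s, sc$ec_reps)
    simulate_recording(montage, sch, sim)
  } else {
    sch <- generate_main_schedule(sc$sessions, sc$trials_per_cond,
                                  sc$rest_range_s,
                                  seed = derive_seed(config$seed, subject,
                                                     "schedule"))
    rec <- simulate_recording(montage, sch, sim)
    inject_blinks(rec, sim$blink_rate, sim$blink_amplitude,
                  seed = derive_seed(config$seed, subject, "blink"))
  }
}

#' Filter and downsample a recording
#'
#' The standard conditioning chain: zero-phase Butterworth bandpass
#' followed by integer decimation.
#'
#' @param recording An `eeg_recording`.
#' @param preprocess Parameter list as in [default_run_config()].
#' @return The conditioned recording.
#' @export
preprocess_recording <- function(recording,
                                 preprocess = default_run_config()$preprocess) {
  rec <- bandpass(recording, preprocess$lo, preprocess$hi, preprocess$order)
  downsample(rec, preprocess$target_fs)
}

# Re-reference the channels of one ROI on the continuous data.
rereference_roi <- function(recording, montage, roi) {
  if (roi == "ear") {
    rereference_ear(recording$data, montage$ear_left, montage$ear_right)
  } else {
    rereference_car(recording$data, roi_channels(montage, roi))
  }
}

#' Run the eyes-closed / eyes-open alpha-SNR study
#'
#' Per subject: simulate the resting paradigm, bandpass and downsample,
#' re-reference per ROI, and compute the EC/EO alpha SNR per ROI. Group
#' level: per-ROI mean and SD plus a Friedman test and pairwise Wilcoxon
#' post-hocs on the subjects x ROIs SNR table.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory; when given, writes
#'   `snr.csv`, `snr_summary.csv`, `snr_stats.csv` and `manifest.json`.
#' @return An `ec_eo_study` list: `snr` (subject x ROI tibble), `summary`,
#'   `friedman`, `posthoc`, `config`.
#' @export
run_ec_eo_study <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  snr <- purrr::map_dfr(seq_len(config$n_subjects), function(s) {
    rec <- simulate_subject(config, s, "ec_eo")
    rec <- preprocess_recording(rec, config$preprocess)
    res <- ec_eo_snr(rec, alpha_band = config$analysis$alpha_band,
                     rois = config$rois)
    message(sprintf("[ec_eo] subject %d: %s", s,
                    paste(sprintf("%s %.2f dB", res$roi, res$snr_db),
                          collapse = ", ")))
    dplyr::mutate(res, subject = s, .before = 1)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(snr, .data$roi),
    mean_snr_db = mean(.data$snr_db), sd_snr_db = stats::sd(.data$snr_db),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(snr[, c("subject", "roi", "snr_db")],
                             names_from = "roi", values_from = "snr_db")
  mat <- as.matrix(wide[, config$rois])
  fr <- if (config$n_subjects >= 2) friedman_test(mat) else NULL
  ph <- if (config$n_subjects >= 2) pairwise_wilcoxon(mat) else NULL
  out <- structure(list(snr = snr, summary = summary, friedman = fr,
                        posthoc = ph, config = config),
                   class = "ec_eo_study")
  if (!is.null(out_dir)) {
    write_study_outputs(out_dir, config, list(
      snr = snr, snr_summary = summary, snr_stats = ph
    ))
  }
  out
}

#' Run the mental-arithmetic vs light-cognitive classification study
#'
#' Per subject and ROI: simulate the main paradigm (with blinks), bandpass
#' and downsample, re-reference the ROI on the continuous data, epoch
#' -2 to 10 s around task onsets, baseline-correct, reject trials by
#' peak-to-peak threshold, and run repeated stratified cross-validation of
#' the multi-band CSP + shrinkage-LDA decoder; optionally also compute the
#' per-condition ROI-averaged ERD/ERS maps. Group level: Friedman test and
#' pairwise Wilcoxon post-hocs on the subjects x ROIs accuracy table.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory; writes `accuracy.csv`,
#'   `accuracy_summary.csv`, `accuracy_stats.csv` and `manifest.json`.
#' @param compute_maps Also compute ERD/ERS maps (slower).
#' @return A `ma_lc_study` list: `accuracy` (subject x ROI tibble),
#'   `summary`, `friedman`, `posthoc`, `maps` (per ROI and condition,
#'   grand-averaged over subjects; `NULL` unless `compute_maps`),
#'   `rejections`, `config`.
#' @export
run_ma_lc_study <- function(config = default_run_config(), out_dir = NULL,
                            compute_maps = FALSE) {
  validate_run_config(config)
  montage <- build_default_montage()
  acc_rows <- list()
  rej_rows <- list()
  map_sum <- list()
  for (s in seq_len(config$n_subjects)) {
    rec <- simulate_subject(config, s, "main")
    rec <- preprocess_recording(rec, config$preprocess)
    for (r in config$rois) {
      dat <- rereference_roi(rec, montage, r)
      rec_r <- rec; rec_r$data <- dat
      ep <- extract_epochs(rec_r, config$preprocess$epoch_window,
                           channels = roi_channels(montage, r))
      ep <- baseline_correct(ep, config$preprocess$baseline)
      rej <- reject_peak_to_peak(ep, config$preprocess$threshold_task)
      kept <- rej$epochs
      n_rej <- table(factor(rej$report$label[!rej$report$kept],
                            levels = c("MA", "LC")))
      message(sprintf("[ma_lc] subject %d %s: %d trials kept, rejected MA %d / LC %d",
                      s, r, n_trials(kept), n_rej[["MA"]], n_rej[["LC"]]))
      cv <- cross_validate(kept, k = config$analysis$k,
                           reps = config$analysis$reps,
                           n_keep = config$analysis$n_keep,
                           seed = derive_seed(config$seed, s, "cv"))
      acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
        subject = s, roi = r, mean_acc = cv$mean, sd_acc = cv$sd,
        n_trials_kept = n_trials(kept)
      )
      rej_rows[[length(rej_rows) + 1]] <- tibble::tibble(
        subject = s, roi = r, n_rejected_ma = n_rej[["MA"]],
        n_rejected_lc = n_rej[["LC"]]
      )
      if (compute_maps) {
        for (cond in c("MA", "LC")) {
          sub <- subset_epochs(kept, trials = which(kept$labels == cond))
          maps <- erders_map(sub, baseline = config$preprocess$baseline,
                             step = config$analysis$erders_step)
          m <- roi_average_map(maps, roi_channels(montage, r))
          key <- paste(r, cond, sep = ".")
          map_sum[[key]] <- if (is.null(map_sum[[key]])) m else {
            m$values <- m$values + map_sum[[key]]$values; m
          }
        }
      }
    }
  }
  accuracy <- dplyr::bind_rows(acc_rows)
  rejections <- dplyr::bind_rows(rej_rows)
  summary <- dplyr::summarise(
    dplyr::group_by(accuracy, .data$roi),
    mean_acc = mean(.data$mean_acc), sd_acc = stats::sd(.data$mean_acc),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(accuracy[, c("subject", "roi", "mean_acc")],
                             names_from = "roi", values_from = "mean_acc")
  mat <- as.matrix(wide[, config$rois])
  fr <- if (config$n_subjects >= 2) friedman_test(mat) else NULL
  ph <- if (config$n_subjects >= 2) pairwise_wilcoxon(mat) else NULL
  maps <- NULL
  if (compute_maps) {
    maps <- purrr::map(map_sum, function(m) {
      m$values <- m$values / config$n_subjects
      m
    })
  }
  out <- structure(list(accuracy = accuracy, summary = summary,
                        friedman = fr, posthoc = ph, maps = maps,
                        rejections = rejections, config = config),
                   class = "ma_lc_study")
  if (!is.null(out_dir)) {
    write_study_outputs(out_dir, config, list(
      accuracy = accuracy, accuracy_summary = summary, accuracy_stats = ph
    ))
  }
  out
}

# CSV outputs plus a manifest holding the full configuration, seed and
# package version -- enough to reproduce the directory exactly.
write_study_outputs <- function(out_dir, config, tables) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  manifest <- list(
    package = "earbci",
    version = as.character(utils::packageVersion("earbci")),
    seed = config$seed,
    config = unclass_config(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$sim <- unclass(cfg$sim)
  cfg
}
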