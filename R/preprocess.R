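# Signal conditioning: zero-phase Butterworth filtering, decimation,
# per-ROI referencing, epoching, baseline correction and peak-to-peak
# artifact rejection.

#' Zero-phase Butterworth bandpass of a recording
#'
#' Filters every channel with a Butterworth bandpass of the given design
#' order, applied forward and backward (zero net phase; squared magnitude
#' response). The default 1-50 Hz band is the standard broadband EEG
#' conditioning ahead of downsampling.
#'
#' @param recording An `eeg_recording`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth design order (applied twice).
#' @return The filtered recording; an attribute `lowpass_hz` records the
#'   upper edge for the decimation safety check.
#' @export
bandpass <- function(recording, lo = 1, hi = 50, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  filt <- butter_design(lo, hi, recording$fs, order)
  recording$data <- zero_phase_rows(recording$data, filt)
  attr(recording, "lowpass_hz") <- hi
  recording
}

#' Downsample a recording by an integer factor
#'
#' Keeps every `fs/target_fs`-th sample. The recording must already be
#' lowpassed below `target_fs/2`; a warning is raised when no prior
#' [bandpass()] is on record or its upper edge exceeds the new Nyquist.
#'
#' @param recording An `eeg_recording`.
#' @param target_fs Target sampling rate; must divide `fs` exactly.
#' @return The decimated recording with updated `fs`.
#' @export
downsample <- function(recording, target_fs = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  fac <- recording$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) {
    abort(sprintf("fs = %g is not an integer multiple of target_fs = %g",
                  recording$fs, target_fs))
  }
  lp <- attr(recording, "lowpass_hz")
  if (is.null(lp) || lp > target_fs / 2) {
    warn("recording not verifiably lowpassed below target_fs/2; aliasing possible")
  }
  fac <- as.integer(round(fac))
  idx <- seq(1L, ncol(recording$data), by = fac)
  recording$data <- recording$data[, idx, drop = FALSE]
  recording$fs <- target_fs
  recording
}

resolve_channels <- function(x, labels) {
  avail <- if (is.matrix(x)) rownames(x) else rownames(x$data)
  miss <- setdiff(labels, avail)
  if (length(miss)) abort(paste("unknown channel(s):", paste(miss, collapse = ", ")))
  labels
}

#' Common average reference over a channel group
#'
#' Subtracts the instantaneous mean of the `group` channels from each group
#' channel; channels outside the group are untouched. Applying the map twice
#' equals applying it once, and the group sums to zero at every sample.
#'
#' @param x A channels x samples matrix with channel rownames, or an
#'   `eeg_recording`.
#' @param group Channel labels of the reference group (non-empty).
#' @return Same type as `x`.
#' @export
rereference_car <- function(x, group) {
  if (inherits(x, "eeg_recording")) {
    x$data <- rereference_car(x$data, group)
    return(x)
  }
  if (!length(group)) abort("group must be non-empty")
  group <- resolve_channels(x, group)
  x[group, ] <- sweep(x[group, , drop = FALSE], 2,
                      colMeans(x[group, , drop = FALSE]))
  x
}

#' Opposite-ear reference for the ear channels
#'
#' Modified common average reference for behind-the-ear electrodes: each
#' left-ear channel is referenced to the mean of the three right-ear
#' channels and vice versa, both computed from the pre-reference values.
#'
#' @param x A channels x samples matrix with rownames, or an `eeg_recording`.
#' @param left,right Labels of the left- and right-ear channels (three each
#'   by convention; other sizes are accepted with `strict = FALSE`).
#' @param strict Require exactly three channels per side.
#' @return Same type as `x`.
#' @export
rereference_ear <- function(x, left, right, strict = TRUE) {
  if (inherits(x, "eeg_recording")) {
    x$data <- rereference_ear(x$data, left, right, strict)
    return(x)
  }
  if (strict && (length(left) != 3 || length(right) != 3)) {
    abort("left and right must each name 3 channels (use strict = FALSE to override)")
  }
  left <- resolve_channels(x, left)
  right <- resolve_channels(x, right)
  ref_l <- colMeans(x[right, , drop = FALSE])   # pre-reference values
  ref_r <- colMeans(x[left, , drop = FALSE])
  x[left, ] <- sweep(x[left, , drop = FALSE], 2, ref_l)
  x[right, ] <- sweep(x[right, , drop = FALSE], 2, ref_r)
  x
}

new_epochs <- function(data, labels, times, fs, channels) {
  structure(list(data = data, labels = labels, times = times, fs = fs,
                 channels = channels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$fs, " Hz\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `eeg_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Extract task epochs from a continuous recording
#'
#' Cuts one epoch per MA/LC task event, on a time axis relative to the task
#' onset. Sample windows are half-open: a `(start, end)` window at sampling
#' rate fs yields exactly `(end - start) * fs` samples.
#'
#' @param recording An `eeg_recording` whose schedule contains `MA`/`LC`
#'   events.
#' @param window Length-2 numeric `(start_s, end_s)` relative to task onset;
#'   the default `(-2, 10)` spans a 2 s pre-task baseline and the 10 s task.
#' @param channels Optional channel subset (default: all).
#' @param task_labels Event labels treated as tasks.
#' @return An `eeg_epochs` object: trials x channels x time array (`data`),
#'   per-trial condition `labels`, `times` axis in seconds, and `fs`.
#' @export
extract_epochs <- function(recording, window = c(-2, 10), channels = NULL,
                           task_labels = c("MA", "LC")) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (window[2] <= window[1]) abort("epoch window must have positive length")
  fs <- recording$fs
  sch <- recording$schedule
  ev <- sch[sch$label %in% task_labels, , drop = FALSE]
  if (!nrow(ev)) abort("schedule contains no task events")
  if (is.null(channels)) channels <- rownames(recording$data)
  channels <- resolve_channels(recording$data, channels)
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  times <- rel / fs
  n_samp <- ncol(recording$data)
  data <- array(NA_real_,
                dim = c(nrow(ev), length(channels), length(rel)),
                dimnames = list(NULL, channels, NULL))
  for (i in seq_len(nrow(ev))) {
    idx <- round(ev$onset_s[i] * fs) + rel + 1L
    if (idx[1] < 1L || idx[length(idx)] > n_samp) {
      abort(sprintf("epoch window for trial %d (%s at %.1f s) exceeds recording bounds",
                    i, ev$label[i], ev$onset_s[i]))
    }
    data[i, , ] <- recording$data[channels, idx, drop = FALSE]
  }
  new_epochs(data, ev$label, times, fs, channels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from the whole epoch. Re-applying with the same window is a no-op.
#'
#' @param epochs An `eeg_epochs`.
#' @param window Length-2 numeric `(start_s, end_s)` inside the epoch time
#'   axis; default `(-2, 0)` (the pre-task interval).
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-2, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) abort("baseline window outside the epoch time axis")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over time (3rd dim)
  epochs
}

#' Peak-to-peak artifact rejection
#'
#' For each trial, takes the maximum over channels of the within-trial
#' amplitude range (max minus min) and removes trials where it strictly
#' exceeds the threshold; a range exactly at the threshold is kept. The
#' default threshold is the mean subject-specific value used for the
#' task-trial screening (126.67 microvolts); the resting-state screening
#' conventionally uses 196.
#'
#' @param epochs An `eeg_epochs`.
#' @param threshold Rejection threshold in microvolts (> 0).
#' @param channels Optional channel subset to search (default: all channels
#'   in the epochs).
#' @return A list with `epochs` (surviving trials) and `report`, a
#'   `rejection_report` tibble with one row per input trial (`trial`,
#'   `label`, `ptp`, `kept`) and attributes `threshold`, `kept_indices`,
#'   `rejected_indices`.
#' @export
reject_peak_to_peak <- function(epochs, threshold = 126.67, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (threshold <= 0) abort("threshold must be > 0")
  if (is.null(channels)) channels <- epochs$channels
  miss <- setdiff(channels, epochs$channels)
  if (length(miss)) abort(paste("unknown channel(s):", paste(miss, collapse = ", ")))
  sub <- epochs$data[, match(channels, epochs$channels), , drop = FALSE]
  ptp <- apply(sub, 1, function(tr) max(apply(tr, 1, function(ch) diff(range(ch)))))
  kept <- which(ptp <= threshold)
  rejected <- which(ptp > threshold)
  if (!length(kept)) {
    abort(sprintf("all %d trials exceed the %.2f uV threshold", length(ptp), threshold))
  }
  report <- tibble::tibble(
    trial = seq_along(ptp), label = epochs$labels, ptp = ptp,
    kept = ptp <= threshold
  )
  attr(report, "threshold") <- threshold
  attr(report, "kept_indices") <- kept
  attr(report, "rejected_indices") <- rejected
  class(report) <- c("rejection_report", class(report))
  out <- epochs
  out$data <- epochs$data[kept, , , drop = FALSE]
  out$labels <- epochs$labels[kept]
  list(epochs = out, report = report)
}

# Subset an epoch set by trial index or channel labels.
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  if (!is.null(trials)) {
    epochs$data <- epochs$data[trials, , , drop = FALSE]
    epochs$labels <- epochs$labels[trials]
  }
  if (!is.null(channels)) {
    epochs$data <- epochs$data[, channels, , drop = FALSE]
    epochs$channels <- channels
  }
  epochs
}
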