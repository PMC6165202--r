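# Time-frequency analysis: short-time Fourier power, the eyes-closed vs
# eyes-open alpha SNR in decibels, and ERD/ERS maps (percent band-power
# change against a pre-task baseline).

#' Short-time Fourier power of one channel
#'
#' Magnitude-squared STFT with a periodic Hann taper. Frames advance by
#' `win_s * (1 - overlap)` seconds; a signal of duration T yields
#' `floor((T - win_s) / step) + 1` frames and the frequency resolution is
#' `1 / win_s`.
#'
#' @param x Numeric vector (one channel), microvolts.
#' @param fs Sampling rate, Hz.
#' @param win_s Window length in seconds (default 1).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A `tf_map`: list with `power` (frequency x time), `freqs` (Hz),
#'   `times` (frame centres, s) and `frame_starts` (frame onsets, s).
#' @export
stft_power <- function(x, fs, win_s = 1, overlap = 0.5) {
  win <- round(win_s * fs)
  if (win < 2) abort("window must contain at least 2 samples")
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  if (length(x) < win) abort("signal shorter than one window")
  step <- max(1L, win - round(overlap * win))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, win - 1) / win))
  frames <- vapply(starts, function(s) x[s:(s + win - 1L)] * taper,
                   numeric(win))
  spec <- stats::mvfft(frames)
  nfreq <- floor(win / 2) + 1L
  power <- Mod(spec[seq_len(nfreq), , drop = FALSE])^2
  structure(
    list(power = power,
         freqs = (seq_len(nfreq) - 1L) * fs / win,
         times = (starts - 1L + win / 2) / fs,
         frame_starts = (starts - 1L) / fs,
         win_s = win / fs),
    class = "tf_map"
  )
}

#' Alpha SNR in decibels
#'
#' `10 * log10(alpha_ec / alpha_eo)`: the eyes-closed over eyes-open mean
#' alpha-band power ratio, in dB.
#'
#' @param alpha_ec,alpha_eo Mean alpha-band powers (strictly positive).
#' @return SNR in dB.
#' @export
#' @examples
#' snr_db(10, 1)  # 10
snr_db <- function(alpha_ec, alpha_eo) {
  if (any(alpha_ec <= 0) || any(alpha_eo <= 0)) {
    abort("powers must be strictly positive")
  }
  10 * log10(alpha_ec / alpha_eo)
}

#' Eyes-closed / eyes-open alpha SNR per region of interest
#'
#' For each ROI: re-reference its channels (common average for the scalp
#' ROIs, opposite-ear reference for the ear ROI), compute the STFT per
#' channel, average alpha-band power over eyes-closed frames and eyes-open
#' frames separately (power-domain average over the ROI channels), and
#' report `snr_db()` of the two. STFT frames are assigned to a condition
#' only if the full window lies inside one block.
#'
#' @param recording A preprocessed (filtered, downsampled) `eeg_recording`
#'   whose schedule contains `EC` and `EO` events.
#' @param montage Montage (defaults to the recording's).
#' @param alpha_band Length-2 numeric band in Hz (default `c(8, 13)`).
#' @param rois ROIs to analyse.
#' @param win_s,overlap STFT parameters.
#' @return A tibble with columns `roi`, `alpha_ec`, `alpha_eo`, `snr_db`.
#' @export
ec_eo_snr <- function(recording, montage = recording$montage,
                      alpha_band = c(8, 13),
                      rois = c("frontal", "central", "occipital", "ear"),
                      win_s = 1, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  sch <- recording$schedule
  for (cond in c("EC", "EO")) {
    if (!any(sch$label == cond)) abort(paste("schedule contains no", cond, "events"))
  }
  purrr::map_dfr(rois, function(r) {
    chans <- roi_channels(montage, r)
    dat <- if (r == "ear") {
      rereference_ear(recording$data, montage$ear_left, montage$ear_right)
    } else {
      rereference_car(recording$data, chans)
    }
    pows <- purrr::map(chans, function(ch) {
      tf <- stft_power(dat[ch, ], recording$fs, win_s, overlap)
      fsel <- tf$freqs >= alpha_band[1] & tf$freqs <= alpha_band[2]
      ec <- frames_in_condition(tf, sch, "EC")
      eo <- frames_in_condition(tf, sch, "EO")
      if (!any(ec) || !any(eo)) abort("no complete STFT frame inside an EC/EO block")
      c(ec = mean(tf$power[fsel, ec]), eo = mean(tf$power[fsel, eo]))
    })
    a_ec <- mean(purrr::map_dbl(pows, "ec"))
    a_eo <- mean(purrr::map_dbl(pows, "eo"))
    tibble::tibble(roi = r, alpha_ec = a_ec, alpha_eo = a_eo,
                   snr_db = snr_db(a_ec, a_eo))
  })
}

# Logical index of STFT frames fully inside a block with the given label.
frames_in_condition <- function(tf, schedule, label) {
  ev <- schedule[schedule$label == label, , drop = FALSE]
  f0 <- tf$frame_starts
  f1 <- f0 + tf$win_s
  sel <- rep(FALSE, length(f0))
  for (i in seq_len(nrow(ev))) {
    sel <- sel | (f0 >= ev$onset_s[i] - 1e-9 &
                    f1 <= ev$onset_s[i] + ev$duration_s[i] + 1e-9)
  }
  sel
}

new_erders_map <- function(values, freqs, times, baseline, label) {
  structure(list(values = values, freqs = freqs, times = times,
                 baseline = baseline, label = label),
            class = "erders_map")
}

#' ERD/ERS maps per channel
#'
#' Event-related (de)synchronization as percent band-power change against
#' the pre-task baseline. Per 1 Hz-wide frequency bin, each trial's channel
#' signal is zero-phase bandpassed and its squared analytic-signal envelope
#' taken as instantaneous power; trial-averaged power `P(f, t)` is then
#' expressed as `100 * (P - R) / R` with `R(f)` the mean over the baseline
#' window. Negative values are ERD, positive values ERS.
#'
#' @param epochs An `eeg_epochs` (typically one condition's trials).
#' @param baseline Length-2 numeric baseline window in seconds.
#' @param freq_range Length-2 numeric `(lo, hi)` in Hz; bins are centred on
#'   `seq(lo, hi, by = step)` with width `step`.
#' @param step Bin width/spacing, Hz.
#' @param order Butterworth design order of the per-bin bandpass.
#' @return A named list (one `erders_map` per channel), each holding a
#'   frequency x time `values` matrix in percent.
#' @export
erders_map <- function(epochs, baseline = c(-2, 0), freq_range = c(1, 50),
                       step = 1, order = 2) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (n_trials(epochs) < 1) abort("empty trial set")
  bsel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(bsel)) abort("baseline window outside epoch time axis")
  centres <- seq(freq_range[1], freq_range[2], by = step)
  fs <- epochs$fs
  nt <- n_trials(epochs)
  ns <- length(epochs$times)
  # reflect-pad each trial by ~2 s so neither the narrowband filter
  # transients nor the circular analytic transform contaminate the epoch
  # (the baseline window sits right at the epoch edge)
  npad <- min(2L * fs, ns - 1L)
  crop <- npad + seq_len(ns)
  maps <- purrr::map(seq_along(epochs$channels), function(ci) {
    vals <- matrix(0, length(centres), ns)
    for (fi in seq_along(centres)) {
      lo <- max(centres[fi] - step / 2, 0.05)
      hi <- min(centres[fi] + step / 2, fs / 2 * 0.99)
      filt <- butter_design(lo, hi, fs, order)
      p <- numeric(ns)
      for (tr in seq_len(nt)) {
        x <- epochs$data[tr, ci, ]
        xp <- c(2 * x[1] - x[(npad + 1L):2L], x,
                2 * x[ns] - x[(ns - 1L):(ns - npad)])
        y <- zero_phase(xp, filt)
        p <- p + analytic_power(y)[crop]
      }
      p <- p / nt
      r <- mean(p[bsel])
      vals[fi, ] <- 100 * (p - r) / r
    }
    new_erders_map(vals, centres, epochs$times, baseline,
                   epochs$channels[ci])
  })
  stats::setNames(maps, epochs$channels)
}

#' Average ERD/ERS maps over a region of interest
#'
#' Element-wise mean of the per-channel maps of the ROI's channels.
#'
#' @param maps Named list of `erders_map` objects as from [erders_map()].
#' @param roi Character vector of channel labels to average.
#' @return A single `erders_map` labelled with the channels averaged.
#' @export
roi_average_map <- function(maps, roi) {
  miss <- setdiff(roi, names(maps))
  if (length(miss)) abort(paste("missing channel map(s):", paste(miss, collapse = ", ")))
  picked <- maps[roi]
  vals <- Reduce(`+`, purrr::map(picked, "values")) / length(picked)
  m1 <- picked[[1]]
  new_erders_map(vals, m1$freqs, m1$times, m1$baseline,
                 paste(roi, collapse = "+"))
}

#' Mean ERD/ERS over a band and time window
#'
#' Convenience summary used to check sign and localization of injected
#' effects: the mean map value over the given frequency band and time
#' window.
#'
#' @param map An `erders_map`.
#' @param band Length-2 numeric frequency band, Hz.
#' @param window Length-2 numeric time window, s.
#' @return Mean percent power change.
#' @export
erders_band_mean <- function(map, band, window = c(0, 10)) {
  fsel <- map$freqs >= band[1] & map$freqs <= band[2]
  tsel <- map$times >= window[1] & map$times < window[2]
  mean(map$values[fsel, tsel])
}
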