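# Synthetic multichannel EEG with known ground truth. The generator mixes
# (i) amplitude-modulated ~10 Hz alpha sources concentrated under the
# parieto-occipital electrodes with weaker centro-frontal satellites,
# (ii) distributed broadband beta/gamma sources, and (iii) per-channel 1/f
# background noise. Source-to-channel weights decay exponentially with 2-D
# electrode distance, so occipital alpha leaks to the ear channels more than
# to central or frontal ones. Condition effects (eyes-closed alpha increase,
# task-related alpha synchronization and beta/gamma desynchronization) are
# multiplicative amplitude envelopes with smooth raised-cosine edges.

#' Simulation configuration
#'
#' Parameters of the synthetic EEG generator. Amplitude-type parameters are
#' in microvolts; gain-type parameters are multiplicative amplitude factors
#' (so a gain g multiplies band power by g^2).
#'
#' @param fs Sampling rate, Hz.
#' @param noise_exponent Slope of the 1/f^exponent background noise PSD.
#' @param noise_scale Background noise RMS per channel, microvolts.
#' @param alpha_freq Centre frequency of the alpha sources, Hz.
#' @param alpha_amplitude Peak amplitude of a unit-weight posterior alpha
#'   source, microvolts.
#' @param roi_alpha_gain Named numeric: extra per-ROI multiplicative gain on
#'   the alpha leakage into that ROI's channels (on top of distance decay).
#' @param ec_alpha_gain Alpha amplitude multiplier while the eyes are closed.
#' @param ma_alpha_ers Alpha amplitude multiplier during mental-arithmetic
#'   task windows (> 1 gives alpha ERS).
#' @param ma_beta_gamma_erd Multiplicative attenuation of beta/gamma source
#'   power during mental arithmetic, in (0, 1] (< 1 gives ERD).
#' @param lc_alpha_gain Mild alpha amplitude multiplier during the
#'   light-cognitive task.
#' @param bg_amplitude RMS of a unit-weight broadband beta/gamma source,
#'   microvolts.
#' @param blink_rate Blink artifacts per minute (used by [inject_blinks()]).
#'   The default models a subject suppressing blinks during trials, so that
#'   roughly 5-10% of 12 s epochs are contaminated, matching typical
#'   task-trial rejection counts.
#' @param blink_amplitude Peak blink deflection at the most frontal
#'   channels, microvolts.
#' @param mixing_spread Exponential decay length of source-to-channel
#'   leakage, in head-radius units.
#' @param envelope_sd Log-sd of the slow lognormal amplitude envelopes
#'   (trial-to-trial and within-trial power variability).
#' @param freq_jitter Maximum slow random-walk deviation of the alpha
#'   frequency, Hz.
#' @param edge_ramp_s Raised-cosine ramp length at condition edges, seconds.
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 1000, noise_exponent = 1, noise_scale = 5,
                       alpha_freq = 10, alpha_amplitude = 2.1,
                       roi_alpha_gain = c(frontal = 1, central = 1,
                                          occipital = 1, ear = 1),
                       ec_alpha_gain = 2, ma_alpha_ers = 1.8,
                       ma_beta_gamma_erd = 0.7, lc_alpha_gain = 1.15,
                       bg_amplitude = 7, blink_rate = 0.5,
                       blink_amplitude = 300, mixing_spread = 0.4,
                       envelope_sd = 0.45, freq_jitter = 0.5,
                       edge_ramp_s = 0.5, seed = NULL) {
  cfg <- list(
    fs = fs, noise_exponent = noise_exponent, noise_scale = noise_scale,
    alpha_freq = alpha_freq, alpha_amplitude = alpha_amplitude,
    roi_alpha_gain = roi_alpha_gain, ec_alpha_gain = ec_alpha_gain,
    ma_alpha_ers = ma_alpha_ers, ma_beta_gamma_erd = ma_beta_gamma_erd,
    lc_alpha_gain = lc_alpha_gain, bg_amplitude = bg_amplitude,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    mixing_spread = mixing_spread, envelope_sd = envelope_sd,
    freq_jitter = freq_jitter, edge_ramp_s = edge_ramp_s, seed = seed
  )
  gains <- c(cfg$ec_alpha_gain, cfg$ma_alpha_ers, cfg$lc_alpha_gain,
             cfg$roi_alpha_gain)
  if (any(gains <= 0)) abort("all gains must be > 0")
  if (cfg$ma_beta_gamma_erd <= 0 || cfg$ma_beta_gamma_erd > 1) {
    abort("ma_beta_gamma_erd must lie in (0, 1]")
  }
  if (fs <= 100) abort("fs must exceed 100 Hz (twice the 50 Hz analysis limit)")
  structure(cfg, class = "sim_config")
}

new_recording <- function(data, fs, montage, schedule) {
  stopifnot(nrow(data) == length(montage$channels))
  rownames(data) <- montage$channels
  structure(list(data = data, fs = fs, montage = montage, schedule = schedule),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1), " s)\n",
      sep = "")
  invisible(x)
}

#' 1/f^exponent (pink-like) background noise
#'
#' Zero-mean noise whose power spectral density follows `1/f^exponent`,
#' independent across channels, unit variance per channel. The spectrum is
#' shaped by a cascade of first-order pole-zero sections with log-spaced
#' corner frequencies, which approximates the target slope to within a few
#' percent across the EEG band; `exponent = 0` returns white noise.
#'
#' @param n_channels,n_samples Output dimensions (`n_samples` >= 2).
#' @param exponent PSD slope (0 = white, 1 = pink).
#' @param seed Optional integer seed.
#' @return `n_channels` x `n_samples` matrix.
#' @export
pink_noise <- function(n_channels, n_samples, exponent = 1, seed = NULL) {
  if (n_samples < 2) abort("n_samples must be >= 2")
  if (n_channels < 1) abort("n_channels must be >= 1")
  gen <- function() {
    out <- matrix(rnorm(n_channels * n_samples), nrow = n_channels)
    if (exponent != 0) {
      sections <- pink_sections(exponent)
      for (ch in seq_len(n_channels)) {
        x <- out[ch, ]
        for (s in sections) x <- iir_pass(s$b, s$a, x)
        out[ch, ] <- x / stats::sd(x)
      }
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# First-order pole-zero cascade approximating |H(f)|^2 ~ f^-exponent.
# Poles log-spaced over normalized frequency 1e-4 .. 0.4 (half-decade
# spacing); each zero sits a fraction exponent/2 of the spacing above its
# pole, giving an average power slope of -10*exponent dB/decade.
pink_sections <- function(exponent) {
  fp <- 10^seq(log10(1e-4), log10(0.4), by = 0.5)
  fz <- fp * 10^(0.5 * exponent / 2)
  lapply(seq_along(fp), function(i) {
    p <- exp(-2 * pi * fp[i])
    z <- exp(-2 * pi * min(fz[i], 0.45))
    list(b = c(1, -z), a = c(1, -p))
  })
}

# Source model: locations (head-schematic coords), relative amplitudes and
# kind. Alpha sources sit under the six occipital ROI electrodes plus
# centro-frontal satellites (alpha is posterior-dominant but present over
# the whole scalp). The eyes-closed gain applies fully to the posterior
# sources and with amplitude exponent 1/2 to the satellites: the
# eyes-closed alpha rise is the posterior rhythm, while task-related alpha
# modulation is widespread. Beta/gamma sources cover all ROI sites.
source_table <- function(montage) {
  co <- montage$coords
  alpha_sites <- c(montage$rois$occipital, "C3", "C4", "F3", "F4")
  alpha_rel <- c(rep(1, 6), 1.10, 1.10, 0.65, 0.65)
  alpha_ec_exp <- c(rep(1, 6), rep(0.5, 4))
  bg_sites <- unlist(montage$rois[c("frontal", "central", "occipital")],
                     use.names = FALSE)
  list(
    alpha = list(x = co[alpha_sites, 1], y = co[alpha_sites, 2],
                 rel = alpha_rel, ec_exp = alpha_ec_exp),
    bg = list(x = co[bg_sites, 1], y = co[bg_sites, 2],
              rel = rep(1, length(bg_sites)))
  )
}

# Per-sample amplitude gain profile for a set of events sharing one gain,
# with raised-cosine ramps of ramp_n samples at the edges.
gain_profile <- function(n, fs, schedule, labels, gain, ramp_s) {
  g <- rep(1, n)
  if (gain == 1) return(g)
  ramp_n <- round(ramp_s * fs)
  up <- raised_cosine(ramp_n)
  ev <- schedule[schedule$label %in% labels, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    i0 <- round(ev$onset_s[i] * fs) + 1L
    i1 <- min(round((ev$onset_s[i] + ev$duration_s[i]) * fs), n)
    if (i0 > n || i1 < i0) next
    prof <- rep(1, i1 - i0 + 1L)
    k <- min(ramp_n, length(prof))
    prof[seq_len(k)] <- up[seq_len(k)]
    prof[length(prof) - seq_len(k) + 1L] <- up[seq_len(k)]
    g[i0:i1] <- g[i0:i1] + (gain - 1) * prof
  }
  g
}

# Slow positive lognormal envelope, normalized to unit mean square.
slow_envelope <- function(n, fs, log_sd, tau_s = 2) {
  e <- exp(log_sd * ou_process(n, tau_s, 1, fs))
  e / sqrt(mean(e^2))
}

#' Simulate a continuous multichannel EEG recording
#'
#' Generates channels x samples data realizing the event schedule under the
#' source-mixing model described in `?sim_config`: occipitally dominant
#' alpha leaking to ear channels with exponential distance decay, broadband
#' beta/gamma activity, 1/f background noise, and multiplicative condition
#' effects (EC alpha increase; MA alpha ERS plus beta/gamma ERD; mild LC
#' alpha gain) ramped smoothly at event edges.
#'
#' @param montage An `eeg_montage`.
#' @param schedule An `eeg_schedule`.
#' @param config A `sim_config`.
#' @return An `eeg_recording` (data in microvolts).
#' @export
simulate_recording <- function(montage, schedule, config = sim_config()) {
  stopifnot(inherits(montage, "eeg_montage"),
            inherits(schedule, "eeg_schedule"),
            inherits(config, "sim_config"))
  gen <- function() simulate_recording_impl(montage, schedule, config)
  if (is.null(config$seed)) gen() else withr::with_seed(config$seed, gen())
}

simulate_recording_impl <- function(montage, schedule, cfg) {
  fs <- cfg$fs
  n <- round(schedule_duration(schedule) * fs)
  co <- montage$coords
  nch <- nrow(co)

  # channel-wise ROI gain for alpha leakage
  roi_gain <- rep(1, nch)
  names(roi_gain) <- rownames(co)
  for (r in names(montage$rois)) {
    g <- cfg$roi_alpha_gain[[r]]
    if (!is.null(g)) roi_gain[montage$rois[[r]]] <- g
  }

  g_task <- gain_profile(n, fs, schedule, "MA", cfg$ma_alpha_ers, cfg$edge_ramp_s) *
    gain_profile(n, fs, schedule, "LC", cfg$lc_alpha_gain, cfg$edge_ramp_s)
  g_ec_full <- gain_profile(n, fs, schedule, "EC", cfg$ec_alpha_gain,
                            cfg$edge_ramp_s)
  g_ec_ant <- gain_profile(n, fs, schedule, "EC", sqrt(cfg$ec_alpha_gain),
                           cfg$edge_ramp_s)
  g_bg <- gain_profile(n, fs, schedule, "MA", sqrt(cfg$ma_beta_gamma_erd),
                       cfg$edge_ramp_s)

  data <- cfg$noise_scale *
    pink_noise(nch, n, exponent = cfg$noise_exponent)

  src <- source_table(montage)
  spread <- cfg$mixing_spread

  # alpha sources: amplitude-modulated sinusoids with slow frequency jitter
  for (i in seq_along(src$alpha$x)) {
    d <- sqrt((co[, 1] - src$alpha$x[i])^2 + (co[, 2] - src$alpha$y[i])^2)
    w <- exp(-d / spread) * roi_gain
    jit <- ou_process(n, tau_s = 5, sigma = cfg$freq_jitter / 2, fs = fs)
    jit <- pmin(pmax(jit, -cfg$freq_jitter), cfg$freq_jitter)
    phase <- 2 * pi * cumsum(cfg$alpha_freq + jit) / fs + runif(1, 0, 2 * pi)
    env <- slow_envelope(n, fs, cfg$envelope_sd)
    g_ec <- if (src$alpha$ec_exp[i] == 1) g_ec_full else g_ec_ant
    s <- (cfg$alpha_amplitude * src$alpha$rel[i]) * env * g_task * g_ec *
      sin(phase)
    sel <- which(w > 0.02)
    data[sel, ] <- data[sel, ] + tcrossprod(w[sel], s)
  }

  # broadband beta/gamma sources: band-limited noise 14-50 Hz
  bp <- butter_design(14, min(50, fs / 2 * 0.98), fs, order = 4)
  for (i in seq_along(src$bg$x)) {
    d <- sqrt((co[, 1] - src$bg$x[i])^2 + (co[, 2] - src$bg$y[i])^2)
    w <- exp(-d / spread)
    x <- iir_pass(bp$b, bp$a, rnorm(n))
    x <- x / stats::sd(x)
    env <- slow_envelope(n, fs, cfg$envelope_sd)
    s <- (cfg$bg_amplitude * src$bg$rel[i]) * env * g_bg * x
    sel <- which(w > 0.02)
    data[sel, ] <- data[sel, ] + tcrossprod(w[sel], s)
  }

  new_recording(data, fs, montage, schedule)
}

#' Inject eye-blink artifacts
#'
#' Adds transient (~300 ms) frontal-dominant deflections at
#' Poisson-distributed times, maximal at Fp1/Fp2 and decaying towards
#' posterior channels. The modified recording carries the injected onset
#' times in its `blink_onsets` attribute (seconds), which downstream
#' artifact-rejection tests use as ground truth.
#'
#' @param recording An `eeg_recording`.
#' @param rate Blink events per minute (>= 0).
#' @param amplitude Peak deflection at the frontopolar channels, microvolts.
#' @param seed Optional integer seed.
#' @param width_s Blink width, seconds.
#' @return The recording with blinks added and attribute `blink_onsets`.
#' @export
inject_blinks <- function(recording, rate = 0.5, amplitude = 300, seed = NULL,
                          width_s = 0.3) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate < 0) abort("rate must be >= 0")
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (rate == 0) {
    attr(recording, "blink_onsets") <- numeric(0)
    return(recording)
  }
  gen <- function() {
    fs <- recording$fs
    dur <- ncol(recording$data) / fs
    n_ev <- rpois(1, rate / 60 * dur)
    onsets <- sort(runif(n_ev, 0, max(dur - width_s, 0)))
    co <- recording$montage$coords
    d <- sqrt((co[, 1] - 0)^2 + (co[, 2] - 1.1)^2)
    w <- exp(-d / 0.35)
    w <- w / max(w)                       # Fp1/Fp2 at full amplitude
    wf <- amplitude * w
    nb <- round(width_s * fs)
    shape <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))
    out <- recording
    for (t0 in onsets) {
      i0 <- round(t0 * fs) + 1L
      idx <- i0:min(i0 + nb - 1L, ncol(out$data))
      out$data[, idx] <- out$data[, idx] +
        tcrossprod(wf, shape[seq_along(idx)])
    }
    attr(out, "blink_onsets") <- onsets
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
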