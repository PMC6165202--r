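# Shared fixtures, built in code. Heavy simulations are cached per session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Recording from a plain matrix, with a trivial one-event schedule.
make_recording <- function(data, fs, montage = NULL, schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- earbci:::new_schedule("REST", 0, ncol(data) / fs)
  }
  if (is.null(montage)) {
    structure(list(data = data, fs = fs, montage = NULL, schedule = schedule),
              class = "eeg_recording")
  } else {
    earbci:::new_recording(data, fs, montage, schedule)
  }
}

# Epoch set straight from an array (for classifier tests).
make_epochs <- function(data, labels, fs = 200, t0 = -2) {
  ns <- dim(data)[3]
  earbci:::new_epochs(
    data, labels, times = t0 + (seq_len(ns) - 1L) / fs, fs = fs,
    channels = dimnames(data)[[2]] %||% paste0("ch", seq_len(dim(data)[2]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-class Gaussian epochs whose classes differ by a variance rescaling of
# the first channel: separable by CSP log-variance by construction.
gaussian_epochs <- function(n_per_class = 20, scale_ma = 3, scale_lc = 1,
                            nc = 6, ns = 2400, fs = 200, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("MA", "LC"), each = n_per_class)
    data <- array(rnorm(2 * n_per_class * nc * ns), c(2 * n_per_class, nc, ns))
    for (i in which(lab == "MA")) data[i, 1, ] <- data[i, 1, ] * scale_ma
    for (i in which(lab == "LC")) data[i, 1, ] <- data[i, 1, ] * scale_lc
    make_epochs(data, lab, fs)
  })
}

# Random symmetric positive-definite matrix.
random_spd <- function(m, seed = NULL) {
  gen <- function() {
    a <- matrix(rnorm(m * m), m)
    crossprod(a) + diag(0.1, m)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Default-effect main-paradigm subject at reduced size (2 sessions), used by
# several spectral/classification tests. Cached: simulated once per run.
small_main_subject <- function() {
  cached("small_main", {
    cfg <- default_run_config(seed = 303, n_subjects = 1,
                              schedule = list(sessions = 2))
    rec <- simulate_subject(cfg, 1, "main")
    preprocess_recording(rec, cfg$preprocess)
  })
}

# Per-ROI referenced, epoched, baseline-corrected, rejected trials of the
# cached small subject.
small_roi_epochs <- function(roi) {
  cached(paste0("small_roi_", roi), {
    pp <- small_main_subject()
    m <- build_default_montage()
    dat <- if (roi == "ear") {
      rereference_ear(pp$data, m$ear_left, m$ear_right)
    } else {
      rereference_car(pp$data, roi_channels(m, roi))
    }
    rec_r <- pp
    rec_r$data <- dat
    ep <- extract_epochs(rec_r, channels = roi_channels(m, roi))
    ep <- baseline_correct(ep)
    reject_peak_to_peak(ep)$epochs
  })
}
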