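# File interchange: 16-bit European Data Format (EDF) for continuous
# recordings (written and read natively -- the format is a fixed-layout
# ASCII header plus little-endian int16 data records), plus a flat binary +
# JSON-sidecar container for epoch sets.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' One data record per second (`fs` samples per channel per record); the
#' recording is truncated to whole seconds. Physical scaling maps the
#' per-channel amplitude range onto the int16 digital range, so the
#' round-trip error is bounded by `range / 65534`. The event schedule is
#' not part of EDF; write it alongside with [write_schedule_csv()].
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  fs <- recording$fs
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) abort("recording shorter than one 1 s data record")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  same <- phys_max - phys_min < 1e-9
  phys_max[same] <- phys_min[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("synthetic", 80),                      # patient id
    edf_pad("earbci simulation", 80),              # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),                                 # record duration, s
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(rownames(data), 16),
    list(rep("AgAgCl electrode", ns), 80),
    list(rep("uV", ns), 8),
    list(sprintf("%.6g", phys_min), 8),
    list(sprintf("%.6g", phys_max), 8),
    list(rep("-32767", ns), 8),
    list(rep("32767", ns), 8),
    list(rep("", ns), 80),
    list(rep(as.character(fs), ns), 8),
    list(rep("", ns), 32)
  )
  for (f in fields) writeChar(paste0(edf_pad(f[[1]], f[[2]]), collapse = ""),
                              con, eos = NULL)
  scale <- 65534 / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round((data[, idx, drop = FALSE] - phys_min) * scale - 32767)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' Reads a 16-bit EDF file with a common sampling rate across channels,
#' returning amplitudes rescaled to physical units. Montage and schedule
#' are attached when supplied (EDF itself carries neither).
#'
#' @param path EDF file path.
#' @param montage Optional `eeg_montage` to attach (channel labels must
#'   match).
#' @param schedule Optional `eeg_schedule` to attach.
#' @return An `eeg_recording` when a montage is given, otherwise a list
#'   with `data`, `fs` and `labels`.
#' @export
read_edf <- function(path, montage = NULL, schedule = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)           # units
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) abort("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- (data - dig_min) * gain + phys_min
  rownames(data) <- labels
  if (is.null(montage)) {
    return(list(data = data, fs = fs, labels = labels))
  }
  if (!identical(labels, montage$channels)) {
    abort("EDF channel labels do not match the montage")
  }
  new_recording(data, fs, montage, schedule)
}

#' Write / read an epoch set as a flat binary matrix with a JSON sidecar
#'
#' The sample data go to `<prefix>.dat` (doubles, trial-major), the
#' metadata (dimensions, labels, time axis, sampling rate, channels) to
#' `<prefix>.json`.
#'
#' @param epochs An `eeg_epochs`.
#' @param prefix Path prefix (without extension).
#' @return `write_epochs()` returns `prefix` invisibly; `read_epochs()`
#'   returns an `eeg_epochs`.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(dim = dim(epochs$data), labels = epochs$labels,
               times = epochs$times, fs = epochs$fs,
               channels = epochs$channels)
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  data <- array(vals, dim = meta$dim,
                dimnames = list(NULL, meta$channels, NULL))
  new_epochs(data, meta$labels, meta$times, meta$fs, meta$channels)
}
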