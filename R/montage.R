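#' Electrode montage for combined scalp and ear EEG
#'
#' The montage used throughout the package: 25 scalp electrodes in 10-20
#' positions plus three electrodes behind each ear (`L1`-`L3`, `R1`-`R3`),
#' 31 channels in total. Four six-channel regions of interest (ROIs) are
#' defined: frontal (Fp1, Fp2, F3, F4, F7, F8), central (FC5, FC6, C3, C4,
#' T7, T8), occipital (P3, P4, PO7, PO8, O1, O2) and ear (R1-R3, L1-L3).
#' Seven scalp channels (Fz, Cz, CP1, CP2, Pz, P7, P8) belong to no ROI.
#' A fifth pseudo-ROI `"scalp"` (all 25 scalp channels, referenced with a
#' 25-channel common average) is available through [roi_channels()] for the
#' all-electrodes reference analysis.
#'
#' Each channel carries an approximate 2-D head-schematic coordinate
#' (unit head radius, x = left to right, y = back to front), used by the
#' synthetic-data generator to model source-to-electrode leakage; the ear
#' electrodes sit posterior-inferior, close to the mastoid.
#'
#' @return An object of class `eeg_montage`: a list with elements
#'   `channels`, `scalp`, `ear_left`, `ear_right`, `rois` (named list of the
#'   four six-channel ROIs) and `coords` (31 x 2 matrix).
#' @export
#' @examples
#' m <- build_default_montage()
#' length(m$channels)       # 31
#' roi_channels(m, "ear")
build_default_montage <- function() {
  coords <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    Fz  = c(0, 0.50),
    F3  = c(-0.42, 0.52), F4 = c(0.42, 0.52),
    F7  = c(-0.81, 0.59), F8 = c(0.81, 0.59),
    FC5 = c(-0.67, 0.27), FC6 = c(0.67, 0.27),
    Cz  = c(0, 0),
    C3  = c(-0.50, 0), C4 = c(0.50, 0),
    T7  = c(-1.00, 0), T8 = c(1.00, 0),
    CP1 = c(-0.26, -0.26), CP2 = c(0.26, -0.26),
    Pz  = c(0, -0.50),
    P3  = c(-0.42, -0.52), P4 = c(0.42, -0.52),
    P7  = c(-0.81, -0.59), P8 = c(0.81, -0.59),
    PO7 = c(-0.56, -0.78), PO8 = c(0.56, -0.78),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95),
    R1  = c(0.95, -0.35), R2 = c(1.00, -0.50), R3 = c(1.03, -0.65),
    L1  = c(-0.95, -0.35), L2 = c(-1.00, -0.50), L3 = c(-1.03, -0.65)
  )
  colnames(coords) <- c("x", "y")
  scalp <- rownames(coords)[1:25]
  rois <- list(
    frontal   = c("Fp1", "Fp2", "F3", "F4", "F7", "F8"),
    central   = c("FC5", "FC6", "C3", "C4", "T7", "T8"),
    occipital = c("P3", "P4", "PO7", "PO8", "O1", "O2"),
    ear       = c("R1", "R2", "R3", "L1", "L2", "L3")
  )
  structure(
    list(
      channels  = rownames(coords),
      scalp     = scalp,
      ear_left  = c("L1", "L2", "L3"),
      ear_right = c("R1", "R2", "R3"),
      rois      = rois,
      coords    = coords
    ),
    class = "eeg_montage"
  )
}

#' Channels of a region of interest
#'
#' @param montage An `eeg_montage`.
#' @param roi One of `"frontal"`, `"central"`, `"occipital"`, `"ear"` or the
#'   pseudo-ROI `"scalp"` (all 25 scalp channels).
#' @return Character vector of channel labels.
#' @export
roi_channels <- function(montage, roi) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (roi == "scalp") return(montage$scalp)
  if (!roi %in% names(montage$rois)) {
    abort(sprintf("unknown ROI '%s'", roi))
  }
  montage$rois[[roi]]
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channels), " channels (",
      length(x$scalp), " scalp + ", length(x$ear_left) + length(x$ear_right),
      " ear)\n", sep = "")
  for (r in names(x$rois)) {
    cat("  ", format(r, width = 9), ": ",
        paste(x$rois[[r]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write / read a montage as JSON
#'
#' Serializes channel labels, ear groups, ROI membership and coordinates.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `write_montage_json()` returns `path` invisibly;
#'   `read_montage_json()` returns an `eeg_montage`.
#' @export
write_montage_json <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  obj <- list(
    channels  = montage$channels,
    scalp     = montage$scalp,
    ear_left  = montage$ear_left,
    ear_right = montage$ear_right,
    rois      = montage$rois,
    coords    = as.data.frame(montage$coords)
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- as.matrix(obj$coords)
  rownames(coords) <- obj$channels
  structure(
    list(
      channels = obj$channels, scalp = obj$scalp,
      ear_left = obj$ear_left, ear_right = obj$ear_right,
      rois = lapply(obj$rois, as.character), coords = coords
    ),
    class = "eeg_montage"
  )
}
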