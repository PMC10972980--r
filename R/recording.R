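#' The 19 scalp electrodes of the international 10-20 montage
#'
#' Modern lead names are used internally; the older temporal names
#' (T3, T4, T5, T6) are accepted on input and normalised to T7, T8, P7, P8.
#'
#' @return Character vector of 19 channel labels in acquisition order.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T7", "T8", "P7", "P8",
    "C3", "C4", "P3", "P4", "O1", "O2", "Fz", "Cz", "Pz")
}

#' @rdname montage_10_20
#' @param labels Character vector of channel labels, possibly in the older
#'   temporal-lead dialect.
#' @export
normalize_channel_labels <- function(labels) {
  legacy <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  idx <- match(toupper(labels), names(legacy))
  out <- ifelse(is.na(idx), labels, unname(legacy[idx]))
  as.character(out)
}

# Approximate planar 10-20 coordinates (unit head circle), used for the
# generator's spatial coupling structure and for edge plots.
montage_coordinates <- function() {
  tibble(
    channel = montage_10_20(),
    x = c(-0.31, 0.31, -0.36, 0.36, -0.81, 0.81, -1.00, 1.00, -0.81, 0.81,
          -0.50, 0.50, -0.36, 0.36, -0.31, 0.31, 0.00, 0.00, 0.00),
    y = c(0.95, 0.95, 0.52, 0.52, 0.59, 0.59, 0.00, 0.00, -0.59, -0.59,
          0.00, 0.00, -0.52, -0.52, -0.95, -0.95, 0.50, 0.00, -0.50)
  )
}

# Binary adjacency of spatially neighbouring electrodes (distance threshold
# on the planar layout). Dense enough that strong local edges form triangles.
montage_adjacency <- function(radius = 0.75) {
  xy <- montage_coordinates()
  d <- as.matrix(stats::dist(cbind(xy$x, xy$y)))
  a <- (d <= radius) * 1
  diag(a) <- 0
  dimnames(a) <- list(xy$channel, xy$channel)
  a
}

#' Construct a multichannel EEG recording
#'
#' The basic substrate of the pipeline: a channels-by-samples matrix in
#' microvolts with channel labels, a sampling rate, and event annotations
#' (half-open intervals, seconds from recording start).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_labels Character vector, one label per row of `data`.
#'   Legacy temporal-lead names are normalised (see
#'   [normalize_channel_labels()]).
#' @param rate_hz Sampling rate in Hz (positive).
#' @param subject_id Identifier string.
#' @param annotations Tibble/data frame with columns `onset_s`,
#'   `duration_s`, `label`, or `NULL` for none. Sorted by onset on
#'   construction; events must end within the recording.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_labels, rate_hz,
                          subject_id = "anonymous", annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_value("`data` must be a numeric matrix (channels x samples).")
  }
  channel_labels <- normalize_channel_labels(as.character(channel_labels))
  if (nrow(data) != length(channel_labels)) {
    abort_value(sprintf(
      "channel count mismatch: %d data rows vs %d labels.",
      nrow(data), length(channel_labels)))
  }
  check_scalar_number(rate_hz, "rate_hz")
  if (rate_hz <= 0) abort_value("`rate_hz` must be positive.")

  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- tibble(onset_s = numeric(), duration_s = numeric(),
                          label = character())
  } else {
    annotations <- as_tibble(annotations)[, c("onset_s", "duration_s", "label")]
    annotations <- dplyr::arrange(annotations, .data$onset_s)
    total_s <- ncol(data) / rate_hz
    if (any(annotations$onset_s < 0) ||
        any(annotations$onset_s + annotations$duration_s > total_s + 1e-9)) {
      abort_value("annotations must lie within the recording duration.")
    }
  }
  rownames(data) <- channel_labels
  structure(
    list(subject_id = subject_id,
         channel_labels = channel_labels,
         rate_hz = rate_hz,
         data = data,
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, nrow(x$annotations)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

recording_duration_s <- function(recording) {
  ncol(recording$data) / recording$rate_hz
}
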