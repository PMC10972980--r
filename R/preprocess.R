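# Filtering, re-referencing, epoching and band decomposition.

#' Construct a state-labelled epoch
#'
#' A fixed-duration slice of a recording, labelled with its seizure state.
#' In the canonical plan, ictal epochs last 5 s and all other states 10 s,
#' with exactly five epochs per (subject, state).
#'
#' @param data Numeric matrix, channels x samples.
#' @param state One of `rest`, `inter_ictal`, `pre_ictal`, `ictal`,
#'   `post_ictal`.
#' @param index Epoch index within its state (1-based).
#' @param rate_hz Sampling rate.
#' @param subject_id Identifier.
#' @param band Optional band name once band-decomposed.
#' @return An `eeg_epoch` object.
#' @export
eeg_epoch <- function(data, state, index, rate_hz, subject_id = "anonymous",
                      band = NULL) {
  states <- c("rest", "inter_ictal", "pre_ictal", "ictal", "post_ictal")
  if (!state %in% states) {
    abort_value(paste0("`state` must be one of: ", paste(states, collapse = ", ")))
  }
  structure(
    list(subject_id = subject_id, state = state, index = as.integer(index),
         duration_s = ncol(data) / rate_hz, data = data, rate_hz = rate_hz,
         band = band),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s %s #%d: %d ch x %d samples (%.1f s)%s\n",
              x$subject_id, x$state, x$index, nrow(x$data), ncol(x$data),
              x$duration_s, if (is.null(x$band)) "" else paste0(" [", x$band, "]")))
  invisible(x)
}

# Hamming-window FIR band-pass design. The transition width defaults to
# max(0.25 * low_hz, 0.5 Hz); the tap count is capped so that short epochs
# can still be filtered (at the cost of a wider transition). Designs are
# memoised: epoch loops reuse the same few filters thousands of times.
.fir_cache <- new.env(parent = emptyenv())

design_fir_bandpass <- function(low_hz, high_hz, rate_hz, max_taps = Inf) {
  key <- paste(low_hz, high_hz, rate_hz, max_taps, sep = "|")
  hit <- .fir_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- design_fir_bandpass_impl(low_hz, high_hz, rate_hz, max_taps)
  .fir_cache[[key]] <- b
  b
}

design_fir_bandpass_impl <- function(low_hz, high_hz, rate_hz, max_taps = Inf) {
  nyq <- rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort_value(sprintf(
      "band edges must satisfy 0 < low (%g) < high (%g) < Nyquist (%g).",
      low_hz, high_hz, nyq))
  }
  trans <- max(0.25 * low_hz, 0.5)
  n_taps <- ceiling(3.3 * rate_hz / trans)
  n_taps <- min(n_taps, max_taps)
  if (n_taps %% 2 == 0) n_taps <- n_taps - 1
  n_taps <- max(n_taps, 9)
  order <- n_taps - 1
  signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass",
               window = signal::hamming(n_taps))
}

# Zero-phase FIR filtering of a channels-x-samples matrix: one FFT
# convolution with the filter's autocorrelation conv(b, b) (equivalent to
# forward-backward application of the symmetric FIR), with odd-symmetric
# edge padding to tame boundary transients.
zero_phase_filter <- function(X, b) {
  n_taps <- length(b)
  N <- ncol(X)
  pad <- min(N - 1L, n_taps)
  left <- 2 * X[, 1] - X[, seq(pad + 1L, 2L), drop = FALSE]
  right <- 2 * X[, N] - X[, seq(N - 1L, N - pad), drop = FALSE]
  Xp <- cbind(left, X, right)
  M <- ncol(Xp)
  g <- stats::convolve(b, rev(b), type = "open")  # conv(b, b), length 2*n_taps - 1
  nfft <- stats::nextn(M + length(g) - 1L)
  G <- fft(c(g, rep(0, nfft - length(g))))
  Zp <- rbind(t(Xp), matrix(0, nfft - M, nrow(X)))
  C <- Re(mvfft(mvfft(Zp) * G, inverse = TRUE)) / nfft
  idx <- pad + n_taps - 1L + seq_len(N)
  out <- t(C[idx, , drop = FALSE])
  dimnames(out) <- dimnames(X)
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed linear-phase FIR applied with zero net phase
#' distortion, so downstream phase estimation is unbiased by filter delay.
#'
#' @param recording An [eeg_recording()] or [eeg_epoch()].
#' @param low_hz,high_hz Band edges; must satisfy
#'   `0 < low_hz < high_hz < rate_hz / 2`.
#' @return Object of the same class with filtered data.
#' @export
bandpass_fir <- function(recording, low_hz, high_hz) {
  if (inherits(recording, "eeg_epoch")) {
    b <- design_fir_bandpass(low_hz, high_hz, recording$rate_hz,
                             max_taps = max(9L, (ncol(recording$data) - 1L) %/% 3L))
    recording$data <- zero_phase_filter(recording$data, b)
    return(recording)
  }
  stopifnot(inherits(recording, "eeg_recording"))
  b <- design_fir_bandpass(low_hz, high_hz, recording$rate_hz,
                           max_taps = max(9L, (ncol(recording$data) - 1L) %/% 3L))
  recording$data <- zero_phase_filter(recording$data, b)
  recording
}

#' Common average reference
#'
#' Subtracts the across-channel mean from every channel at each sample, so
#' the per-sample channel mean of the output is exactly zero.
#'
#' @param recording An [eeg_recording()] or [eeg_epoch()] with >= 2 channels.
#' @return Re-referenced object of the same class.
#' @export
common_average_reference <- function(recording) {
  data <- recording$data
  if (nrow(data) < 2) abort_value("common average reference needs >= 2 channels.")
  recording$data <- sweep(data, 2, colMeans(data))
  recording
}

#' Artifact-removal hook
#'
#' The synthetic generator produces artifact-free data, so the default
#' pipeline applies no artifact correction. This hook is the insertion
#' point for ocular/muscle artifact removal when real recordings are
#' analysed; supplying a function swaps it in.
#'
#' @param recording An [eeg_recording()].
#' @param method `"none"` (identity) or a function `recording -> recording`.
#' @return The (possibly cleaned) recording.
#' @export
artifact_removal_hook <- function(recording, method = "none") {
  if (is.function(method)) return(method(recording))
  recording
}

#' Extract state-labelled epochs from a recording
#'
#' Window rules: ictal epochs are the first `dur` seconds of each annotated
#' seizure; pre-ictal windows end at seizure onset; post-ictal windows
#' start at seizure offset; inter-ictal windows must keep at least
#' `guard_s` seconds away from every seizure; rest windows (controls) may
#' lie anywhere. Windows of one state never overlap and are taken earliest
#' first.
#'
#' @param recording An [eeg_recording()].
#' @param state Target state.
#' @param n_epochs Number of epochs required (default 5).
#' @param dur_s Epoch duration; defaults to 5 s for ictal, 10 s otherwise.
#' @param guard_s Inter-ictal guard distance from any seizure (default 60).
#' @return List of [eeg_epoch()] objects of length `n_epochs`.
#' @export
extract_epochs <- function(recording, state, n_epochs = 5,
                           dur_s = if (state == "ictal") 5 else 10,
                           guard_s = 60) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- recording$rate_hz
  total_s <- recording_duration_s(recording)
  ann <- recording$annotations
  seiz <- ann[ann$label == "seizure", , drop = FALSE]

  starts <- switch(
    state,
    ictal = {
      ok <- seiz$duration_s >= dur_s - 1e-9
      seiz$onset_s[ok]
    },
    pre_ictal = {
      s <- seiz$onset_s - dur_s
      s[s >= -1e-9]
    },
    post_ictal = {
      s <- seiz$onset_s + seiz$duration_s
      s[s + dur_s <= total_s + 1e-9]
    },
    inter_ictal = ,
    rest = {
      if (state == "inter_ictal" && nrow(seiz) > 0) {
        blocked <- cbind(pmax(0, seiz$onset_s - guard_s),
                         pmin(total_s, seiz$onset_s + seiz$duration_s + guard_s))
        free <- free_intervals(blocked, total_s)
      } else {
        free <- matrix(c(0, total_s), 1, 2)
      }
      unlist(apply(free, 1, function(iv) {
        if (iv[2] - iv[1] < dur_s) return(numeric(0))
        seq(iv[1], iv[2] - dur_s, by = dur_s)
      }, simplify = FALSE))
    },
    abort_value(paste0("unknown state: ", state))
  )

  # earliest-first, non-overlapping
  starts <- sort(starts)
  chosen <- numeric(0)
  for (s in starts) {
    if (length(chosen) == 0 || s >= max(chosen) + dur_s - 1e-9) {
      chosen <- c(chosen, s)
    }
    if (length(chosen) == n_epochs) break
  }
  if (length(chosen) < n_epochs) {
    abort_insufficient(sprintf(
      "subject %s: only %d qualifying %s window(s), %d required.",
      recording$subject_id, length(chosen), state, n_epochs))
  }

  n_samp <- as.integer(round(dur_s * rate))
  lapply(seq_along(chosen), function(i) {
    from <- as.integer(round(chosen[i] * rate))
    eeg_epoch(recording$data[, from + seq_len(n_samp), drop = FALSE],
              state = state, index = i, rate_hz = rate,
              subject_id = recording$subject_id)
  })
}

# Complement of a union of [start, end] intervals within [0, total].
free_intervals <- function(blocked, total_s) {
  blocked <- blocked[order(blocked[, 1]), , drop = FALSE]
  merged <- blocked[1, , drop = FALSE]
  for (i in seq_len(nrow(blocked))[-1]) {
    if (blocked[i, 1] <= merged[nrow(merged), 2]) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], blocked[i, 2])
    } else {
      merged <- rbind(merged, blocked[i, ])
    }
  }
  edges <- c(0, as.vector(t(merged)), total_s)
  out <- matrix(edges, ncol = 2, byrow = TRUE)
  out[out[, 2] - out[, 1] > 1e-9, , drop = FALSE]
}

#' Decompose an epoch into frequency bands
#'
#' One zero-phase FIR band-passed copy of the epoch per band, same shape.
#' The epoch is expected to be broadband-filtered and re-referenced
#' already.
#'
#' @param epoch An [eeg_epoch()].
#' @param bands Band table from [frequency_bands()].
#' @return Named list of band-filtered [eeg_epoch()] objects.
#' @export
band_decompose <- function(epoch, bands = frequency_bands()) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    ep <- bandpass_fir(epoch, bands$low_hz[i], bands$high_hz[i])
    ep$band <- bands$band[i]
    ep
  })
  names(out) <- bands$band
  out
}
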