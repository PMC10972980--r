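# Phase-locking-value connectivity: analytic signal via the Hilbert
# transform, and the symmetric channel-by-channel PLV matrix
#   PLV = (1/N) | sum_n exp(i * theta_n) |
# where theta_n is the instantaneous phase difference and N the number of
# valid samples in the epoch.

# Discrete analytic signal z = s + i * H[s] via the FFT half-spectrum method.
analytic_transform <- function(X) {
  # X: channels x samples (real); returns complex matrix of same shape
  n <- ncol(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  t(mvfft(mvfft(t(X)) * h, inverse = TRUE)) / n
}

#' Analytic signal of a band-limited series
#'
#' Computes z(t) = s(t) + i H\[s\](t) with the Hilbert transform H, giving
#' the instantaneous amplitude |z| and phase arg(z). The leading and
#' trailing `trim_fraction` of samples are marked invalid (Hilbert edge
#' transients) and excluded from downstream PLV sums.
#'
#' @param series Real numeric vector, length >= 16, band-limited.
#' @param trim_fraction Fraction of samples to trim at each end, in
#'   \[0, 0.25\] (default 0.1).
#' @return An `analytic_signal` object with fields `z`, `amplitude`,
#'   `phase` (in (-pi, pi\]) and logical `valid`.
#' @export
analytic_signal <- function(series, trim_fraction = 0.1) {
  if (length(series) < 16) abort_value("`series` must have at least 16 samples.")
  check_scalar_number(trim_fraction, "trim_fraction", 0, 0.25)
  z <- drop(analytic_transform(matrix(series, nrow = 1)))
  n <- length(series)
  k <- floor(trim_fraction * n)
  valid <- rep(TRUE, n)
  if (k > 0) valid[c(seq_len(k), n - seq_len(k) + 1L)] <- FALSE
  structure(
    list(z = z, amplitude = Mod(z), phase = Arg(z), valid = valid),
    class = "analytic_signal")
}

#' Phase-locking value of two phase series
#'
#' The modulus of the mean unit complex exponential of the phase
#' difference: 1 for a constant phase lag (perfect locking), 0 for phase
#' differences spread uniformly on the circle.
#'
#' @param phase_x,phase_y Equal-length numeric vectors of instantaneous
#'   phase (radians).
#' @return A number in \[0, 1\].
#' @export
plv_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    abort_value("phase vectors must have equal length.")
  }
  if (length(phase_x) < 1) abort_value("need at least one phase sample.")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' PLV matrix of a band-filtered epoch
#'
#' All channel pairs via the analytic signal; entries lie in \[0, 1\], the
#' matrix is symmetric and the diagonal is exactly 1.
#'
#' @param band_epoch An [eeg_epoch()] already filtered to one band.
#' @param band Band name; defaults to the epoch's `band` field.
#' @param trim_fraction Edge-trim fraction passed to the analytic signal.
#' @return A `plv_matrix` object: `values` (n_ch x n_ch), `band`, `state`,
#'   `subject_id`, `n_segments` (valid samples) and `epoch_index`.
#' @export
plv_matrix <- function(band_epoch, band = NULL, trim_fraction = 0.1) {
  stopifnot(inherits(band_epoch, "eeg_epoch"))
  band <- band %||% band_epoch$band %||% "broadband"
  X <- band_epoch$data
  n <- ncol(X)
  k <- floor(trim_fraction * n)
  keep <- if (k > 0) seq(k + 1L, n - k) else seq_len(n)
  Z <- analytic_transform(X)[, keep, drop = FALSE]
  U <- Z / Mod(Z)  # unit phasors exp(i * phase)
  M <- Mod(U %*% Conj(t(U))) / length(keep)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(rownames(X), rownames(X))
  new_plv_matrix(M, band = band, state = band_epoch$state,
                 subject_id = band_epoch$subject_id,
                 n_segments = length(keep),
                 epoch_index = band_epoch$index)
}

new_plv_matrix <- function(values, band, state, subject_id, n_segments,
                           epoch_index) {
  structure(
    list(values = values, band = band, state = state,
         subject_id = subject_id, n_segments = n_segments,
         epoch_index = epoch_index),
    class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<plv_matrix> %s/%s/%s epoch %s: %d nodes, mean off-diagonal PLV %.3f\n",
              x$subject_id, x$state, x$band, as.character(x$epoch_index),
              nrow(x$values), mean(off)))
  invisible(x)
}

#' Entry-wise mean of PLV matrices
#'
#' Averages matched per-epoch matrices into one per-subject, per-state,
#' per-band matrix (`epoch_index = "mean"`). All inputs must share
#' subject, state and band.
#'
#' @param matrices List of [plv_matrix()] objects.
#' @return A `plv_matrix` with `epoch_index = "mean"`.
#' @export
average_plv <- function(matrices) {
  if (length(matrices) == 0) abort_value("`matrices` must be non-empty.")
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "plv_matrix"))
    if (!identical(m$band, ref$band) || !identical(m$state, ref$state) ||
        !identical(m$subject_id, ref$subject_id)) {
      abort_value("all matrices must share subject, state and band.")
    }
  }
  values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  new_plv_matrix(values, band = ref$band, state = ref$state,
                 subject_id = ref$subject_id,
                 n_segments = sum(vapply(matrices, `[[`, 1, "n_segments")),
                 epoch_index = "mean")
}

#' Tidy a PLV matrix into a long edge table
#'
#' @param x A [plv_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per upper-triangle edge: `subject_id`,
#'   `state`, `band`, `epoch`, `ch1`, `ch2`, `plv`.
#' @method tidy plv_matrix
#' @export
tidy.plv_matrix <- function(x, ...) {
  labs <- rownames(x$values) %||% as.character(seq_len(nrow(x$values)))
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    subject_id = x$subject_id, state = x$state, band = x$band,
    epoch = as.character(x$epoch_index),
    ch1 = labs[ut[, 1]], ch2 = labs[ut[, 2]],
    plv = x$values[ut])
}
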