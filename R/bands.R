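#' Canonical EEG frequency bands
#'
#' The five analysis bands used throughout the package: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-13 Hz), beta1 (13-30 Hz) and beta2 (30-45 Hz).
#'
#' @param names Character vector selecting a subset of the canonical bands,
#'   in the order requested.
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' frequency_bands()
#' frequency_bands(c("theta", "alpha"))
#' @export
frequency_bands <- function(names = c("delta", "theta", "alpha", "beta1", "beta2")) {
  canon <- tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2"),
    low_hz = c(1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 45)
  )
  bad <- setdiff(names, canon$band)
  if (length(bad) > 0) {
    abort_value(paste0("Unknown band(s): ", paste(bad, collapse = ", ")))
  }
  canon[match(names, canon$band), ]
}

band_center_hz <- function(band_row) (band_row$low_hz + band_row$high_hz) / 2
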