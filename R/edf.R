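# EDF / EDF+C (16-bit) reader and writer.
#
# The format is a 256-byte ASCII header, 256 ASCII bytes per signal, then
# fixed-duration data records of little-endian int16 samples. Annotations
# travel in an "EDF Annotations" signal as TALs:
#   +onset[\x15duration]\x14label\x14 ... \x00
# One-second records are used on write; recordings are zero-padded to a
# whole number of records.

EDF_PHYS_RANGE_UV <- 1000
EDF_DIG_MAX <- 32767L

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording to an EDF/EDF+ file
#'
#' Samples are quantised to 16 bits over a declared physical range
#' (default +/- 1000 microvolts, the usual clinical scalp-EEG dialect), so
#' the round trip is exact up to half a quantisation step. Annotations, if
#' present, are serialised to an `EDF Annotations` signal (making the file
#' EDF+C).
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @param physical_max_uv Declared symmetric physical range in microvolts.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path, physical_max_uv = EDF_PHYS_RANGE_UV) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  if (!all(is.finite(x))) abort_value("recording contains non-finite samples.")
  if (max(abs(x)) > physical_max_uv) {
    abort_value(sprintf(
      "sample amplitude %.1f uV exceeds the declared physical range +/-%g uV.",
      max(abs(x)), physical_max_uv))
  }
  rate <- recording$rate_hz
  if (abs(rate - round(rate)) > 1e-9) {
    abort_value("write_edf uses 1 s data records; `rate_hz` must be an integer.")
  }
  spr <- as.integer(round(rate))
  n_ch <- nrow(x)

  n_records <- as.integer(ceiling(ncol(x) / spr))
  if (ncol(x) < n_records * spr) {
    x <- cbind(x, matrix(0, n_ch, n_records * spr - ncol(x)))
  }

  has_annot <- nrow(recording$annotations) > 0
  annot_raw <- NULL
  annot_spr <- 0L
  if (has_annot) {
    annot_raw <- build_annotation_records(recording$annotations, n_records)
    annot_spr <- length(annot_raw[[1]]) %/% 2L
  }
  ns <- n_ch + as.integer(has_annot)

  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste(recording$subject_id, "X X X"), 80),
    pad_field("Startdate 01-JAN-2020 X X X", 80),
    pad_field("01.01.20", 8),
    pad_field("00.00.00", 8),
    num_field(256 * (ns + 1), 8),
    pad_field(if (has_annot) "EDF+C" else "", 44),
    num_field(n_records, 8),
    num_field(1, 8),
    num_field(ns, 4)
  )
  labels <- recording$channel_labels
  if (has_annot) labels <- c(labels, "EDF Annotations")
  sig <- function(vals, width) paste(vapply(vals, pad_field, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    sig(labels, 16),
    sig(rep("", ns), 80),
    sig(c(rep("uV", n_ch), if (has_annot) ""), 8),
    sig(c(rep(-physical_max_uv, n_ch), if (has_annot) -1), 8),
    sig(c(rep(physical_max_uv, n_ch), if (has_annot) 1), 8),
    sig(c(rep(-EDF_DIG_MAX, n_ch), if (has_annot) -32768), 8),
    sig(c(rep(EDF_DIG_MAX, n_ch), if (has_annot) 32767), 8),
    sig(rep("", ns), 80),
    sig(c(rep(spr, n_ch), if (has_annot) annot_spr), 8),
    sig(rep("", ns), 32)
  )
  writeBin(charToRaw(hdr), con)

  gain <- physical_max_uv / EDF_DIG_MAX
  dig <- matrix(as.integer(pmin(pmax(round(x / gain), -EDF_DIG_MAX), EDF_DIG_MAX)),
                nrow = n_ch)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
    if (has_annot) writeBin(annot_raw[[r]], con)
  }
  invisible(path)
}

# One raw vector of TAL bytes per record, all equal length (even).
# Each TAL ends with \x14 and TALs are NUL-terminated per the EDF+ spec.
build_annotation_records <- function(annotations, n_records) {
  recs <- lapply(seq_len(n_records) - 1L, function(r) {
    tals <- list(charToRaw(sprintf("+%d\x14\x14", r)))
    sel <- annotations$onset_s >= r & annotations$onset_s < r + 1
    if (any(sel)) {
      a <- annotations[sel, ]
      tals <- c(tals, lapply(seq_len(nrow(a)), function(i) {
        charToRaw(sprintf("+%.4f\x15%.4f\x14%s\x14",
                          a$onset_s[i], a$duration_s[i], a$label[i]))
      }))
    }
    do.call(c, lapply(tals, function(t) c(t, as.raw(0))))
  })
  width <- max(vapply(recs, length, 1L)) + 2L
  width <- width + width %% 2L
  lapply(recs, function(r) c(r, raw(width - length(r))))
}

#' Read an EDF/EDF+ file
#'
#' @param path Path to an EDF or EDF+C file.
#' @param strict_19 If `TRUE`, error unless the file carries exactly the 19
#'   data channels of the 10-20 montage.
#' @return An [eeg_recording()]; annotations are parsed from any
#'   `EDF Annotations` signal (empty otherwise).
#' @export
read_edf <- function(path, strict_19 = FALSE) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))

  fixed <- rawToChar(readBin(con, "raw", 256))
  if (nchar(fixed) < 256) abort_format("truncated EDF header.")
  fld <- function(s, from, len) substr(s, from, from + len - 1)
  version <- trimws(fld(fixed, 1, 8))
  if (version != "0") abort_format("invalid EDF header: version field must be '0'.")
  patient <- trimws(fld(fixed, 9, 80))
  n_records <- suppressWarnings(as.integer(trimws(fld(fixed, 237, 8))))
  record_dur <- suppressWarnings(as.numeric(trimws(fld(fixed, 245, 8))))
  ns <- suppressWarnings(as.integer(trimws(fld(fixed, 253, 4))))
  if (is.na(ns) || ns < 1) abort_format("invalid EDF header: signal count (ns).")
  if (is.na(n_records) || n_records < 1) abort_format("invalid EDF header: number of records.")
  if (is.na(record_dur) || record_dur <= 0) abort_format("invalid EDF header: record duration.")

  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  if (nchar(sig_hdr) < 256L * ns) abort_format("truncated EDF signal header.")
  take <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset * ns + (i - 1) * width + 1,
                    offset * ns + i * width))
    }, "")
  }
  labels <- take(0, 16)
  phys_min <- as.numeric(take(16 + 80 + 8, 8))
  phys_max <- as.numeric(take(16 + 80 + 8 + 8, 8))
  dig_min <- as.numeric(take(16 + 80 + 8 + 16, 8))
  dig_max <- as.numeric(take(16 + 80 + 8 + 24, 8))
  spr <- as.integer(take(16 + 80 + 8 + 32 + 80, 8))
  if (any(is.na(spr)) || any(spr < 1)) abort_format("invalid EDF header: samples per record.")
  if (any(is.na(dig_max - dig_min)) || any(dig_max == dig_min)) {
    abort_format("invalid EDF header: digital min/max.")
  }

  total_per_rec <- sum(spr) * 2L
  payload <- readBin(con, "raw", total_per_rec * n_records)
  if (length(payload) < total_per_rec * n_records) abort_format("truncated EDF data.")

  offsets <- c(0L, cumsum(spr * 2L))
  is_annot <- labels == "EDF Annotations"

  sig_bytes <- function(i) {
    base <- (seq_len(n_records) - 1L) * total_per_rec + offsets[i]
    idx <- as.vector(outer(seq_len(spr[i] * 2L), base, "+"))
    payload[idx]
  }

  data_idx <- which(!is_annot)
  if (strict_19 && length(data_idx) != 19) {
    abort_value(sprintf("expected 19 data channels, found %d.", length(data_idx)))
  }
  rate <- spr[data_idx] / record_dur
  if (length(unique(rate)) > 1) {
    abort_format("mixed per-signal sampling rates are not supported.")
  }
  data <- matrix(0, length(data_idx), spr[data_idx[1]] * n_records)
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    dig <- readBin(sig_bytes(i), "integer", n = spr[i] * n_records,
                   size = 2, signed = TRUE, endian = "little")
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[k, ] <- (dig - dig_min[i]) * gain + phys_min[i]
  }

  annotations <- NULL
  if (any(is_annot)) {
    tal_raw <- do.call(c, lapply(which(is_annot), sig_bytes))
    annotations <- parse_tal_annotations(tal_raw)
  }

  subject_id <- strsplit(patient, "\\s+")[[1]][1]
  if (is.na(subject_id) || subject_id == "" || subject_id == "X") subject_id <- "anonymous"

  eeg_recording(data, labels[data_idx], rate[1], subject_id = subject_id,
                annotations = annotations)
}

parse_tal_annotations <- function(raw_bytes) {
  # Split the byte stream on NULs (TAL terminators), then each TAL on \x14.
  zero <- which(raw_bytes == as.raw(0))
  starts <- c(1L, zero + 1L)
  ends <- c(zero - 1L, length(raw_bytes))
  out <- list()
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    tal <- rawToChar(raw_bytes[starts[k]:ends[k]])
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    labels_k <- parts[-1]
    labels_k <- labels_k[nzchar(labels_k)]
    if (length(labels_k) == 0) next  # record-timestamp TAL
    time <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(time[1]))
    dur <- if (length(time) > 1) suppressWarnings(as.numeric(time[2])) else 0
    if (is.na(onset)) next
    out[[length(out) + 1L]] <- tibble(onset_s = onset, duration_s = dur,
                                      label = labels_k)
  }
  if (length(out) == 0) return(NULL)
  dplyr::arrange(dplyr::bind_rows(out), .data$onset_s)
}

#' Export epochs as whitespace-delimited text matrices
#'
#' One file per epoch, samples in rows and channels in columns, with a
#' header row of channel labels. Filenames encode subject, state and epoch
#' index (`<subject>_<state>_ep<index>.txt`).
#'
#' @param epochs A non-empty list of [eeg_epoch()] objects.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
export_epochs_text <- function(epochs, dir) {
  if (length(epochs) == 0) abort_value("`epochs` must be a non-empty list.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(epochs, function(ep) {
    stopifnot(inherits(ep, "eeg_epoch"))
    path <- file.path(dir, sprintf("%s_%s_ep%02d.txt",
                                   ep$subject_id, ep$state, ep$index))
    m <- t(ep$data)
    colnames(m) <- rownames(ep$data)
    write.table(m, path, quote = FALSE, row.names = FALSE, col.names = TRUE)
    path
  }, "")
  invisible(paths)
}
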