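# Synthetic 19-channel EEG cohort generator.
#
# Band-limited oscillations come from a noisy mean-field (Kuramoto) phase
# ensemble whose global coupling K is set per seizure state and per band --
# the generative ground truth the PLV pipeline must recover -- plus a fixed
# montage-adjacency local coupling that gives non-ictal networks their
# lattice-like spatial structure. Ictal segments superimpose a 2.5-4 Hz
# spike-and-slow-wave discharge on strongly coupled oscillations; all
# segments ride on 1/f background noise.

#' Default per-state, per-band global coupling profile
#'
#' Inter-ictal, pre-ictal, post-ictal and rest share one moderate coupling
#' value so that only the ictal state separates statistically; ictal
#' coupling is far above the others in every band.
#'
#' @param bands Tibble from [frequency_bands()].
#' @param baseline,ictal Coupling strengths (dimensionless Kuramoto K).
#' @return Tibble with columns `state`, `band`, `coupling_K`.
#' @export
default_coupling_profile <- function(bands = frequency_bands(),
                                     baseline = 2, ictal = 12) {
  states <- c("rest", "inter_ictal", "pre_ictal", "ictal", "post_ictal")
  tidyr::expand_grid(state = states, band = bands$band) |>
    dplyr::mutate(coupling_K = ifelse(.data$state == "ictal", ictal, baseline))
}

#' Configuration of a synthetic cohort
#'
#' Houses every free parameter of the generator. Defaults describe the
#' study conditions emulated throughout the package: 36 patients and 36
#' controls at 500 Hz, five 10 s epochs per state (5 s ictal), coupling
#' elevated only during seizures, and a 1/f background.
#'
#' @param n_jae,n_hc Group sizes (>= 1).
#' @param rate_hz Sampling rate (integer Hz).
#' @param bands Band table from [frequency_bands()].
#' @param epoch_plan List with `n_epochs`, per-state epoch durations
#'   `dur_s` (ictal must be shorter), an inter-ictal guard distance and the
#'   gap inserted between consecutive seizure blocks, all in seconds.
#' @param coupling_by_state_band Tibble `(state, band, coupling_K)`; ictal
#'   coupling must be >= every other state in every band.
#' @param k_local Strength of the fixed montage-adjacency coupling
#'   (state-independent).
#' @param sigma_phi Phase-noise scale, rad/sqrt(s).
#' @param freq_spread_hz SD of the static per-channel natural-frequency
#'   detuning around each band centre; detuning is what decorrelates
#'   channels when coupling is weak.
#' @param ictal_spared_channels Channels only partially recruited into the
#'   ictal hypersynchrony (generalized spike-wave discharges are
#'   fronto-centrally dominant; posterior/temporal leads are relatively
#'   spared).
#' @param ictal_spared_gain Coupling gain (0-1) of the spared channels
#'   during ictal segments.
#' @param amp_jitter Half-width of the uniform per-channel, per-band
#'   amplitude jitter (relative).
#' @param phase_lag_sd SD (radians) of the static per-channel phase lag of
#'   each band's oscillation. Amplitude gradients and small zero-mean
#'   conduction lags are what let globally synchronous activity survive
#'   common-average re-referencing, as on real scalp recordings.
#' @param amplitude_scales_uv Named per-band oscillation amplitudes.
#' @param swd_amplitude_uv Spike-wave discharge amplitude during seizures.
#' @param noise_spectrum_exponent Exponent of the 1/f^a background.
#' @param noise_scale_uv RMS of the background noise.
#' @param seed Master seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_jae = 36, n_hc = 36, rate_hz = 500,
                          bands = frequency_bands(),
                          epoch_plan = list(
                            n_epochs = 5,
                            dur_s = c(rest = 10, inter_ictal = 10, pre_ictal = 10,
                                      ictal = 5, post_ictal = 10),
                            inter_ictal_guard_s = 60,
                            seizure_gap_s = 2),
                          coupling_by_state_band = default_coupling_profile(bands),
                          k_local = 0, sigma_phi = 1.2, freq_spread_hz = 0.05,
                          ictal_spared_channels = c("T7", "T8", "P7", "P8", "O1", "O2"),
                          ictal_spared_gain = 0.1,
                          amp_jitter = 0.4, phase_lag_sd = 0.8,
                          amplitude_scales_uv = c(delta = 20, theta = 15, alpha = 20,
                                                  beta1 = 8, beta2 = 5),
                          swd_amplitude_uv = 80,
                          noise_spectrum_exponent = 1,
                          noise_scale_uv = 12,
                          seed = 1L) {
  stopifnot(n_jae >= 1, n_hc >= 1, rate_hz > 0)
  cpl <- as_tibble(coupling_by_state_band)
  if (any(cpl$coupling_K < 0)) abort_value("coupling strengths must be >= 0.")
  by_band <- split(cpl, cpl$band)
  for (b in names(by_band)) {
    k_ict <- by_band[[b]]$coupling_K[by_band[[b]]$state == "ictal"]
    if (length(k_ict) != 1 || any(k_ict < by_band[[b]]$coupling_K)) {
      abort_value(sprintf(
        "ictal coupling must be >= every other state's coupling (band %s).", b))
    }
  }
  missing_amp <- setdiff(bands$band, names(amplitude_scales_uv))
  if (length(missing_amp) > 0) {
    abort_value(paste0("amplitude_scales_uv missing band(s): ",
                       paste(missing_amp, collapse = ", ")))
  }
  structure(
    list(n_jae = as.integer(n_jae), n_hc = as.integer(n_hc),
         rate_hz = rate_hz, bands = bands, epoch_plan = epoch_plan,
         coupling_by_state_band = cpl, k_local = k_local,
         sigma_phi = sigma_phi, freq_spread_hz = freq_spread_hz,
         ictal_spared_channels = ictal_spared_channels,
         ictal_spared_gain = ictal_spared_gain,
         amp_jitter = amp_jitter, phase_lag_sd = phase_lag_sd,
         amplitude_scales_uv = amplitude_scales_uv,
         swd_amplitude_uv = swd_amplitude_uv,
         noise_spectrum_exponent = noise_spectrum_exponent,
         noise_scale_uv = noise_scale_uv, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Coupled band-limited phase signals
#'
#' Generates `n_channels` signals cos(phi_i(t)) whose phases follow a noisy
#' mean-field coupled-oscillator update around the band's centre frequency,
#' each channel carrying a small static natural-frequency detuning. The
#' pairwise PLV of the output increases monotonically with `coupling_K`,
#' from ~0 (uncoupled oscillators drift apart through detuning and phase
#' noise) towards 1 (strong coupling entrains all channels).
#'
#' @param n_channels Number of channels.
#' @param band One-row band tibble (see [frequency_bands()]).
#' @param coupling_K Global coupling strength (>= 0).
#' @param duration_s,rate_hz Signal length and sampling rate.
#' @param seed RNG seed (deterministic output).
#' @param sigma_phi Phase-noise scale, rad/sqrt(s).
#' @param freq_spread_hz SD of the per-channel frequency detuning (Hz).
#' @param k_local,adjacency Optional local coupling over a fixed binary
#'   adjacency (defaults off).
#' @return Numeric matrix `[n_channels x n_samples]`.
#' @export
coupled_phase_signals <- function(n_channels, band, coupling_K, duration_s,
                                  rate_hz, seed, sigma_phi = 1.2,
                                  freq_spread_hz = 0.6,
                                  k_local = 0, adjacency = NULL) {
  if (coupling_K < 0) abort_value("`coupling_K` must be >= 0.")
  n <- as.integer(round(duration_s * rate_hz))
  if (n < 2) abort_value("duration_s * rate_hz must be at least 2 samples.")
  if (is.null(adjacency)) adjacency <- matrix(0, 1, 1)
  withr::with_seed(seed, {
    phi0 <- runif(n_channels, 0, 2 * pi)
    f_chan <- band_center_hz(band) + rnorm(n_channels, 0, freq_spread_hz)
    ph <- kuramoto_integrate(n_channels, n, 1 / rate_hz, f_chan,
                             coupling_K, adjacency, k_local, sigma_phi, phi0,
                             rep(1, n_channels))
  })
  cos(ph)
}

#' Spike-and-slow-wave discharge template
#'
#' A periodic absence-seizure caricature: each cycle is a narrow (~70 ms)
#' biphasic spike followed by a half-sine slow wave filling the remainder
#' of the cycle, demeaned cycle-wise so any integer number of cycles has
#' zero mean. Only the cycle rate is physiological (2.5-4 Hz in juvenile
#' absence epilepsy); the morphology is a conventional caricature.
#'
#' @param freq_hz Cycle rate in Hz, in [2, 5].
#' @param duration_s,rate_hz Output length and sampling rate.
#' @return Numeric vector of length `round(duration_s * rate_hz)`, peak
#'   spike amplitude 1.
#' @export
swd_waveform <- function(freq_hz, duration_s, rate_hz) {
  if (!is_scalar_number(freq_hz) || freq_hz < 2 || freq_hz > 5) {
    abort_value("`freq_hz` must lie in [2, 5] Hz.")
  }
  cycle_len <- max(4L, as.integer(round(rate_hz / freq_hz)))
  spike_len <- max(2L, as.integer(round(0.07 * rate_hz)))
  spike_len <- min(spike_len, cycle_len - 2L)
  slow_len <- cycle_len - spike_len
  spike <- sin(2 * pi * seq_len(spike_len) / (spike_len + 1))
  slow <- 0.45 * sin(pi * seq_len(slow_len) / (slow_len + 1))
  cycle <- c(spike, slow)
  cycle <- cycle - mean(cycle)
  n <- as.integer(round(duration_s * rate_hz))
  rep_len(cycle, n)
}

# 1/f^a Gaussian background via spectral shaping, one channel per row.
pink_noise_matrix <- function(n_channels, n_samples, exponent, scale_uv, rate_hz) {
  freqs <- seq(0, n_samples - 1) / n_samples * rate_hz
  freqs <- pmin(freqs, rate_hz - freqs)
  shape <- c(0, freqs[-1]^(-exponent / 2))
  out <- matrix(0, n_channels, n_samples)
  for (i in seq_len(n_channels)) {
    spec <- fft(rnorm(n_samples)) * shape
    x <- Re(fft(spec, inverse = TRUE)) / n_samples
    out[i, ] <- x / sd(x) * scale_uv
  }
  out
}

# Timeline of coupling segments for one subject, as a tibble
# (state, dur_s, is_seizure); seizure annotations are derived from it.
subject_timeline <- function(group, epoch_plan) {
  dur <- epoch_plan$dur_s
  n_ep <- epoch_plan$n_epochs
  if (group == "HC") {
    return(tibble(state = "rest", dur_s = n_ep * dur[["rest"]] + 10,
                  is_seizure = FALSE))
  }
  inter_block <- n_ep * dur[["inter_ictal"]] + 2 + epoch_plan$inter_ictal_guard_s
  segs <- list(tibble(state = "inter_ictal", dur_s = inter_block,
                      is_seizure = FALSE))
  for (k in seq_len(n_ep)) {
    segs[[length(segs) + 1L]] <- tibble(
      state = c("pre_ictal", "ictal", "post_ictal", "inter_ictal"),
      dur_s = c(dur[["pre_ictal"]], dur[["ictal"]], dur[["post_ictal"]],
                epoch_plan$seizure_gap_s),
      is_seizure = c(FALSE, TRUE, FALSE, FALSE))
  }
  dplyr::bind_rows(segs)
}

#' Generate one subject's synthetic recording
#'
#' Patients (`group == "JAE"`) get an inter-ictal background block followed
#' by five seizure blocks (pre-ictal / ictal / post-ictal), each ictal
#' segment carrying the subject's spike-wave discharge on top of strongly
#' coupled oscillations, with `seizure` annotations; controls get rest
#' signal only, annotated `rest`. Deterministic given `seed`.
#'
#' @param subject One-row tibble (or list) with `subject_id`, `group`
#'   (`"JAE"`/`"HC"`), `sex`, `age_years`, `discharge_pattern` and, for
#'   patients, `swd_freq_hz`.
#' @param config A [cohort_config()].
#' @param seed Per-subject seed.
#' @return An [eeg_recording()].
#' @export
generate_subject_recording <- function(subject, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- montage_10_20()
  n_ch <- length(labels)
  rate <- config$rate_hz
  timeline <- subject_timeline(subject$group, config$epoch_plan)
  seg_n <- as.integer(round(timeline$dur_s * rate))
  n_total <- sum(seg_n)
  adj <- montage_adjacency()
  cpl <- config$coupling_by_state_band
  gain_base <- rep(1, n_ch)
  gain_ictal <- ifelse(labels %in% config$ictal_spared_channels,
                       config$ictal_spared_gain, 1)

  withr::with_seed(seed, {
    data <- pink_noise_matrix(n_ch, n_total, config$noise_spectrum_exponent,
                              config$noise_scale_uv, rate)
    for (b in seq_len(nrow(config$bands))) {
      band <- config$bands[b, ]
      amp <- config$amplitude_scales_uv[[band$band]]
      k_by_state <- cpl$coupling_K[cpl$band == band$band]
      names(k_by_state) <- cpl$state[cpl$band == band$band]
      phi <- runif(n_ch, 0, 2 * pi)
      f_chan <- band_center_hz(band) + rnorm(n_ch, 0, config$freq_spread_hz)
      amp_ch <- amp * runif(n_ch, 1 - config$amp_jitter, 1 + config$amp_jitter)
      psi_ch <- rnorm(n_ch, 0, config$phase_lag_sd)
      pos <- 0L
      for (s in seq_len(nrow(timeline))) {
        len <- seg_n[s]
        if (len == 0L) next
        gain <- if (timeline$state[s] == "ictal") gain_ictal else gain_base
        ph <- kuramoto_integrate(n_ch, len + 1L, 1 / rate, f_chan,
                                 k_by_state[[timeline$state[s]]],
                                 adj, config$k_local, config$sigma_phi, phi,
                                 gain)
        data[, pos + seq_len(len)] <- data[, pos + seq_len(len)] +
          amp_ch * cos(ph[, seq_len(len), drop = FALSE] + psi_ch)
        phi <- ph[, len + 1L]
        pos <- pos + len
      }
    }
    # spike-wave discharges during seizures, bilaterally synchronous with
    # mild per-channel amplitude variation
    if (subject$group == "JAE") {
      chan_scale <- runif(n_ch, 0.85, 1.15) * gain_ictal^0.5
      seg_start <- cumsum(c(0L, seg_n[-length(seg_n)]))
      for (s in which(timeline$is_seizure)) {
        wav <- swd_waveform(subject$swd_freq_hz, timeline$dur_s[s], rate)
        idx <- seg_start[s] + seq_along(wav)
        data[, idx] <- data[, idx] +
          config$swd_amplitude_uv * outer(chan_scale, wav)
      }
    }
  })

  seg_onset <- cumsum(c(0, timeline$dur_s[-nrow(timeline)]))
  annotations <- if (subject$group == "JAE") {
    tibble(onset_s = seg_onset[timeline$is_seizure],
           duration_s = timeline$dur_s[timeline$is_seizure],
           label = "seizure")
  } else {
    tibble(onset_s = 0, duration_s = sum(timeline$dur_s), label = "rest")
  }
  eeg_recording(data, labels, rate, subject_id = subject$subject_id,
                annotations = annotations)
}

# Truncated-normal ages via rejection sampling.
rtruncnorm_ages <- function(n, mean, sd, lower = 5, upper = 30) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Atypical discharge rates: uniform over [2.5, 4] excluding the 3 Hz notch.
draw_atypical_freq <- function(n) {
  lo_w <- 2.9 - 2.5
  hi_w <- 4.0 - 3.1
  pick_hi <- runif(n) < hi_w / (lo_w + hi_w)
  ifelse(pick_hi, runif(n, 3.1, 4.0), runif(n, 2.5, 2.9))
}

#' Generate a full synthetic cohort
#'
#' Subject covariates approximate the emulated study's margins: ages from
#' truncated normals (patients 11.33 +/- 5.26 y, controls 12.83 +/- 3.26 y,
#' range 5-30), sexes 21/15 male/female in patients and 22/14 in controls
#' at n = 36 (proportional otherwise), discharge subtype 21 typical-3 Hz vs
#' 15 atypical. Per-subject seeds are derived from the master seed, so the
#' cohort is a pure function of its configuration.
#'
#' @param config A [cohort_config()].
#' @param keep_recordings If `FALSE`, the `recording` column is omitted
#'   (covariates only), which is cheap when a pipeline streams subjects.
#' @return Tibble with columns `subject_id`, `group`, `sex`, `age_years`,
#'   `discharge_pattern`, `swd_freq_hz`, `handedness`, `seed` and (unless
#'   dropped) a `recording` list-column of [eeg_recording()] objects.
#' @export
generate_cohort <- function(config, keep_recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- cohort_subjects(config)
  if (keep_recordings) {
    subjects$recording <- purrr::map(seq_len(nrow(subjects)), function(i) {
      generate_subject_recording(subjects[i, ], config, subjects$seed[i])
    })
  }
  subjects
}

# Covariate table only (deterministic in config$seed).
cohort_subjects <- function(config) {
  n_jae <- config$n_jae
  n_hc <- config$n_hc
  withr::with_seed(config$seed, {
    n_male_jae <- round(n_jae * 21 / 36)
    n_male_hc <- round(n_hc * 22 / 36)
    n_typical <- round(n_jae * 21 / 36)
    jae <- tibble(
      subject_id = sprintf("jae%02d", seq_len(n_jae)),
      group = "JAE",
      sex = sample(rep(c("male", "female"), c(n_male_jae, n_jae - n_male_jae))),
      age_years = rtruncnorm_ages(n_jae, 11.33, 5.26),
      discharge_pattern = sample(rep(c("typical_3Hz", "atypical"),
                                     c(n_typical, n_jae - n_typical))))
    jae$swd_freq_hz <- ifelse(jae$discharge_pattern == "typical_3Hz", 3,
                              draw_atypical_freq(n_jae))
    hc <- tibble(
      subject_id = sprintf("hc%02d", seq_len(n_hc)),
      group = "HC",
      sex = sample(rep(c("male", "female"), c(n_male_hc, n_hc - n_male_hc))),
      age_years = rtruncnorm_ages(n_hc, 12.83, 3.26),
      discharge_pattern = "none",
      swd_freq_hz = NA_real_)
    out <- dplyr::bind_rows(jae, hc)
    out$handedness <- "right"
    out$seed <- derive_seeds(config$seed + 1L, nrow(out))
    out
  })
}

#' @rdname generate_cohort
#' @param cohort A cohort tibble from [generate_cohort()].
#' @export
cohort_manifest <- function(cohort) {
  dplyr::select(as_tibble(cohort), -dplyr::any_of(c("recording", "seed")))
}
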