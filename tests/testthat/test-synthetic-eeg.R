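alpha_band <- frequency_bands("alpha")

mean_pairwise_plv <- function(X, rate_hz = 500) {
  m <- plv_matrix(toy_epoch(X, rate_hz = rate_hz), band = "alpha")$values
  mean(m[upper.tri(m)])
}

test_that("coupling strength controls pairwise synchrony at both extremes", {
  plv_k0 <- mean(vapply(1:20, function(s)
    mean_pairwise_plv(coupled_phase_signals(19, alpha_band, 0, 10, 500, s)),
    numeric(1)))
  expect_lt(plv_k0, 0.2)
  plv_k50 <- mean(vapply(1:20, function(s)
    mean_pairwise_plv(coupled_phase_signals(19, alpha_band, 50, 10, 500, 100 + s)),
    numeric(1)))
  expect_gte(plv_k50, 0.95)
})

test_that("mean PLV rises monotonically with coupling across the K grid", {
  grid <- c(0, 1, 2, 5, 10, 50)
  means <- vapply(seq_along(grid), function(g) {
    mean(vapply(1:50, function(s) {
      X <- coupled_phase_signals(12, alpha_band, grid[g], 8, 250, 1000 * g + s)
      mean_pairwise_plv(X, rate_hz = 250)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(means, seq_along(grid), method = "spearman"), 0.9)
})

test_that("negative coupling and degenerate durations are rejected", {
  expect_error(coupled_phase_signals(5, alpha_band, -1, 1, 500, 1),
               class = "jaenet_error_value")
  expect_error(coupled_phase_signals(5, alpha_band, 1, 0.001, 500, 1),
               class = "jaenet_error_value")
})

test_that("spike-wave template has the right cycle count, spectrum and mean", {
  w <- swd_waveform(3, 1, 500)
  expect_length(w, 500)
  peaks <- which(diff(sign(diff(w))) == -2) + 1
  big <- peaks[w[peaks] > 0.7 * max(w)]
  expect_length(big, 3)

  w10 <- swd_waveform(3, 10, 500)
  spec <- Mod(fft(w10))[2:2500]
  f <- (1:2499) / 10
  expect_lt(abs(f[which.max(spec)] - 3), 0.1)

  cyc <- round(500 / 3)
  w3 <- swd_waveform(3, 3 * cyc / 500, 500)
  expect_lt(abs(mean(w3)), 1e-6 * max(abs(w3)))

  expect_error(swd_waveform(1.5, 1, 500), class = "jaenet_error_value")
  expect_error(swd_waveform(6, 1, 500), class = "jaenet_error_value")
})

test_that("patient recordings carry five 5 s seizures; controls none", {
  cfg <- cohort_config(n_jae = 1, n_hc = 1, rate_hz = 250,
                       epoch_plan = reduced_epoch_plan(), seed = 5)
  subs <- jaenet:::cohort_subjects(cfg)
  jae <- subs[subs$group == "JAE", ][1, ]
  hc <- subs[subs$group == "HC", ][1, ]

  rec <- generate_subject_recording(jae, cfg, 99)
  seiz <- rec$annotations[rec$annotations$label == "seizure", ]
  expect_gte(nrow(seiz), 5)
  expect_true(all(seiz$duration_s == cfg$epoch_plan$dur_s[["ictal"]]))

  rec_hc <- generate_subject_recording(hc, cfg, 98)
  expect_equal(sum(rec_hc$annotations$label == "seizure"), 0)
  expect_true("rest" %in% rec_hc$annotations$label)

  # determinism: same subject, config and seed give bit-identical data
  again <- generate_subject_recording(jae, cfg, 99)
  expect_identical(rec$data, again$data)
  expect_identical(rec$annotations, again$annotations)
})

test_that("cohort composition matches the emulated study margins", {
  cfg <- cohort_config(n_jae = 36, n_hc = 36, rate_hz = 250,
                       epoch_plan = reduced_epoch_plan(), seed = 3)
  subs <- jaenet:::cohort_subjects(cfg)
  expect_equal(nrow(subs), 72)
  expect_equal(sum(subs$group == "JAE"), 36)
  expect_equal(as.vector(table(subs$sex[subs$group == "JAE"])[c("male", "female")]),
               c(21L, 15L))
  expect_equal(as.vector(table(subs$sex[subs$group == "HC"])[c("male", "female")]),
               c(22L, 14L))
  expect_equal(sum(subs$discharge_pattern == "typical_3Hz"), 21)
  expect_equal(sum(subs$discharge_pattern == "atypical"), 15)
  expect_true(all(subs$age_years >= 5 & subs$age_years <= 30))
  expect_true(all(subs$swd_freq_hz[subs$discharge_pattern == "typical_3Hz"] == 3))
  aty <- subs$swd_freq_hz[subs$discharge_pattern == "atypical"]
  expect_true(all(aty >= 2.5 & aty <= 4 & abs(aty - 3) > 0.05))

  # a small cohort is a pure function of its config
  small <- cohort_config(n_jae = 2, n_hc = 2, rate_hz = 250,
                         epoch_plan = reduced_epoch_plan(), seed = 8)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(c1$subject_id, c2$subject_id)
  expect_identical(c1$recording[[1]]$data, c2$recording[[1]]$data)
})

test_that("ictal epochs are more phase-locked than inter-ictal in every patient", {
  cfg <- cohort_config(n_jae = 3, n_hc = 1, rate_hz = 250,
                       epoch_plan = reduced_epoch_plan(), seed = 21)
  subs <- jaenet:::cohort_subjects(cfg)
  for (i in which(subs$group == "JAE")) {
    rec <- generate_subject_recording(subs[i, ], cfg, subs$seed[i])
    rec <- common_average_reference(bandpass_fir(rec, 1, 45))
    band_mean <- function(state) {
      eps <- extract_epochs(rec, state, 5, dur_s = 5, guard_s = 15)
      mean(vapply(eps, function(ep) {
        m <- plv_matrix(bandpass_fir(ep, 8, 13), band = "alpha")$values
        mean(m[upper.tri(m)])
      }, numeric(1)))
    }
    expect_gt(band_mean("ictal") - band_mean("inter_ictal"), 0)
  }
})

test_that("background noise follows the configured 1/f spectral slope", {
  x <- withr::with_seed(4, jaenet:::pink_noise_matrix(1, 60 * 250, 1, 10, 250))
  n <- length(x)
  spec <- Mod(fft(drop(x)))[2:(n / 2)]^2
  f <- (1:(n / 2 - 1)) * 250 / n
  sel <- f >= 2 & f <= 40
  fit <- lm(log(spec[sel]) ~ log(f[sel]))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.5)
})

test_that("config validation enforces the ictal-coupling ground truth", {
  prof <- default_coupling_profile()
  prof$coupling_K[prof$state == "ictal"] <- 0.5
  expect_error(cohort_config(coupling_by_state_band = prof),
               class = "jaenet_error_value")
})
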