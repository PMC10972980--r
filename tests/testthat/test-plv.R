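test_that("analytic signal recovers amplitude and phase of pure tones", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  a <- analytic_signal(cos(2 * pi * 10 * t))
  expect_lt(max(abs(a$amplitude[a$valid] - 1)), 0.01)
  dphi <- diff(a$phase)
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi[a$valid[-1] & a$valid[-length(a$valid)]] -
                      2 * pi * 10 / rate)), 1e-3)
  expect_equal(Re(a$z), cos(2 * pi * 10 * t), tolerance = 1e-10)
  expect_equal(Mod(a$z * exp(-1i * a$phase)), a$amplitude, tolerance = 1e-12)

  # sine lags cosine by pi/2 everywhere in the valid region
  b <- analytic_signal(sin(2 * pi * 10 * t))
  lag <- (a$phase - b$phase + pi) %% (2 * pi) - pi
  expect_lt(max(abs(lag[a$valid] - pi / 2)), 1e-6)

  expect_error(analytic_signal(rnorm(8)), class = "jaenet_error_value")
})

test_that("analytic amplitude tracks a known modulation envelope", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  env <- 1 + 0.5 * cos(2 * pi * 1 * t)
  a <- analytic_signal(env * cos(2 * pi * 10 * t))
  err <- a$amplitude[a$valid] - env[a$valid]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(env[a$valid]^2)), 0.05)
})

test_that("phase-locking value boundary identities hold", {
  set.seed(6)
  phi <- cumsum(rnorm(5000, sd = 0.1))
  expect_identical(plv_pair(phi, phi + pi / 4), 1)
  theta <- 2 * pi * (1:360) / 360
  expect_lt(plv_pair(theta, rep(0, 360)), 1e-12)
  expect_equal(plv_pair(phi, phi), 1)
  expect_error(plv_pair(1:3, 1:4), class = "jaenet_error_value")
})

test_that("PLV matches a brute-force complex sum and the Rayleigh null level", {
  # direct evaluation on a toy phase pair
  withr::with_seed(7, {
    px <- runif(8, -pi, pi)
    py <- runif(8, -pi, pi)
  })
  brute <- Mod(sum(complex(argument = px - py))) / 8
  expect_equal(plv_pair(px, py), brute, tolerance = 1e-12)

  # E[PLV] for independent uniform phases ~ sqrt(pi)/(2 sqrt(N))
  n <- 5000
  draws <- withr::with_seed(8, vapply(1:100, function(i)
    plv_pair(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi)), numeric(1)))
  expected <- sqrt(pi) / 2 / sqrt(n)
  expect_lt(abs(mean(draws) - expected) / expected, 0.2)
})

test_that("PLV is invariant to global phase offsets of one channel", {
  rate <- 250
  X <- coupled_phase_signals(4, frequency_bands("alpha"), 3, 4, rate, 13)
  m1 <- plv_matrix(toy_epoch(X, rate_hz = rate), band = "alpha")$values
  a <- analytic_signal(X[1, ])
  # shift channel 1 by a constant phase via its analytic representation
  X2 <- X
  X2[1, ] <- Re(a$z * exp(1i * 1.1))
  m2 <- plv_matrix(toy_epoch(X2, rate_hz = rate), band = "alpha")$values
  expect_equal(m1, m2, tolerance = 5e-3)
})

test_that("PLV matrices are symmetric, unit-diagonal and permutation-covariant", {
  rate <- 250
  X <- coupled_phase_signals(6, frequency_bands("theta"), 2, 4, rate, 3)
  ep <- toy_epoch(X, rate_hz = rate)
  M <- plv_matrix(ep, band = "theta")
  expect_true(all(M$values >= 0 & M$values <= 1))
  expect_identical(M$values, t(M$values))
  expect_true(all(diag(M$values) == 1))
  expect_equal(M$band, "theta")

  # identical channels lock perfectly
  same <- toy_epoch(matrix(rep(X[1, ], 3), 3, byrow = TRUE), rate_hz = rate)
  expect_equal(plv_matrix(same)$values, matrix(1, 3, 3),
               ignore_attr = TRUE, tolerance = 1e-9)

  # relabelling symmetry: P M P^T for permuted input
  perm <- c(3, 1, 6, 2, 5, 4)
  Mp <- plv_matrix(toy_epoch(X[perm, ], rate_hz = rate), band = "theta")
  expect_equal(Mp$values, M$values[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("independent broadband channels give a near-zero off-diagonal PLV", {
  offs <- vapply(1:20, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(19 * 10 * 250), 19))
    bp <- bandpass_fir(toy_epoch(X, rate_hz = 250), 1, 45)
    m <- plv_matrix(bp, band = "broadband")$values
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_lt(mean(offs), 0.1)
})

test_that("epoch-mean matrices average entries and preserve validity", {
  mk <- function(v) jaenet:::new_plv_matrix(
    matrix(c(1, v, v, 1), 2), band = "alpha", state = "ictal",
    subject_id = "s", n_segments = 100, epoch_index = 1)
  avg <- average_plv(list(mk(0.2), mk(0.6)))
  expect_equal(avg$values[1, 2], 0.4)
  expect_equal(avg$epoch_index, "mean")

  five <- replicate(5, mk(0.3), simplify = FALSE)
  expect_equal(average_plv(five)$values, mk(0.3)$values)

  other <- mk(0.5)
  other$band <- "theta"
  expect_error(average_plv(list(mk(0.2), other)), class = "jaenet_error_value")

  # convexity: averages of valid PLV matrices stay valid
  rate <- 250
  mats <- lapply(1:5, function(s) {
    X <- coupled_phase_signals(5, frequency_bands("alpha"), 2, 2, rate, s)
    plv_matrix(toy_epoch(X, rate_hz = rate), band = "alpha")
  })
  av <- average_plv(mats)
  expect_true(all(av$values >= 0 & av$values <= 1))
  expect_identical(av$values, t(av$values))
})

test_that("tidy() produces the long edge table", {
  X <- coupled_phase_signals(4, frequency_bands("alpha"), 2, 2, 250, 1)
  rownames(X) <- c("Fp1", "Fp2", "Cz", "Pz")
  td <- tidy(plv_matrix(toy_epoch(X, rate_hz = 250, state = "ictal"),
                        band = "alpha"))
  expect_equal(nrow(td), 6)
  expect_named(td, c("subject_id", "state", "band", "epoch", "ch1", "ch2", "plv"))
  expect_true(all(td$plv >= 0 & td$plv <= 1))
})
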