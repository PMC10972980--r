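# Brute-force oracles, kept deliberately naive (triple loops, explicit
# path relaxation) and independent of the package's C++ kernels.

brute_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

brute_path_length <- function(W) {
  D <- brute_distances(W)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

brute_global_efficiency <- function(W) {
  D <- brute_distances(W)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

brute_clustering <- function(W) {
  n <- nrow(W)
  wmax <- max(W[row(W) != col(W)])
  if (wmax <= 0) return(list(node = rep(NA_real_, n), mean = 0))
  A <- W / wmax
  ci <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbrs <- which(W[i, ] > 0 & seq_len(n) != i)
    k <- length(nbrs)
    if (k < 2) next
    s <- 0
    for (j in nbrs) for (l in nbrs) {
      if (j != l) s <- s + (A[i, j] * A[i, l] * A[j, l])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  m <- if (all(is.na(ci))) 0 else mean(ci, na.rm = TRUE)
  list(node = ci, mean = m)
}

brute_local_efficiency <- function(W) {
  n <- nrow(W)
  total <- 0
  for (i in seq_len(n)) {
    nbrs <- which(W[i, ] > 0 & seq_len(n) != i)
    if (length(nbrs) < 2) next
    total <- total + brute_global_efficiency(W[nbrs, nbrs, drop = FALSE])
  }
  total / n
}

# Small-world index recomputed from the documented null scheme: permute
# the upper-triangle weights (same RNG recipe as null_model_config) and
# evaluate C and L on every surrogate with the brute-force oracles.
brute_small_world <- function(W, n_surrogates, seed) {
  n <- nrow(W)
  m <- n * (n - 1) / 2
  perms <- withr::with_seed(seed,
    vapply(seq_len(n_surrogates), function(i) sample.int(m), integer(m)))
  up <- W[upper.tri(W)]
  Cs <- numeric(n_surrogates)
  Ls <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    Ws <- matrix(0, n, n)
    Ws[upper.tri(Ws)] <- up[perms[, s]]
    Ws <- Ws + t(Ws)
    Cs[s] <- brute_clustering(Ws)$mean
    Ls[s] <- brute_path_length(Ws)
  }
  (brute_clustering(W)$mean / mean(Cs)) / (brute_path_length(W) / mean(Ls))
}

# Random symmetric weight matrix with a zero diagonal; optionally sparse.
random_weight_matrix <- function(n, p_zero = 0, seed = NULL) {
  gen <- function() {
    w <- runif(n * (n - 1) / 2, 0.05, 1)
    if (p_zero > 0) w[runif(length(w)) < p_zero] <- 0
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- w
    W + t(W)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Epoch carrying an arbitrary signal matrix (test scaffolding).
toy_epoch <- function(data, rate_hz = 500, state = "rest", index = 1,
                      band = NULL) {
  eeg_epoch(data, state = state, index = index, rate_hz = rate_hz,
            subject_id = "toy", band = band)
}

# |H(f)|^2 of a designed FIR applied forward-backward, at frequency f_hz.
filter_gain_squared <- function(b, f_hz, rate_hz) {
  k <- seq_along(b) - 1
  Mod(sum(b * exp(-2i * pi * f_hz * k / rate_hz)))^2
}

reduced_epoch_plan <- function() {
  list(n_epochs = 5,
       dur_s = c(rest = 5, inter_ictal = 5, pre_ictal = 5, ictal = 5,
                 post_ictal = 5),
       inter_ictal_guard_s = 15, seizure_gap_s = 2)
}
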