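# Weighted graph-theory metrics of PLV networks.
#
# Analysis is fully weighted and dense (no thresholding/binarisation by
# default): PLV matrices are strictly positive so every metric is
# well-defined. Edge lengths are inverse weights d = 1/w; clustering is the
# Onnela geometric-mean variant on max-normalised weights; the small-world
# index is referenced to a weight-permutation null ensemble (dense
# matrices have no topology to rewire).

as_weight_matrix <- function(W, threshold = 0) {
  if (inherits(W, "plv_matrix")) W <- W$values
  if (!is.matrix(W) || !is.numeric(W)) abort_value("`W` must be a numeric matrix.")
  if (nrow(W) != ncol(W)) abort_value("`W` must be square.")
  if (max(abs(W - t(W))) > 1e-8) abort_value("`W` must be symmetric.")
  if (any(W < 0)) abort_value("weights must be non-negative.")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (threshold > 0) W[W < threshold] <- 0
  W
}

#' Weighted clustering coefficient (Onnela variant)
#'
#' Geometric-mean triangle intensity per node on weights normalised by the
#' maximum off-diagonal weight; the network coefficient is the mean over
#' nodes with at least two neighbours.
#'
#' @param W Symmetric non-negative weight matrix or [plv_matrix()].
#' @param threshold Optional absolute weight threshold (defaults off).
#' @return List with `node` (per-node coefficients, `NA` where degree < 2)
#'   and `mean` (network coefficient).
#' @export
weighted_clustering <- function(W, threshold = 0) {
  W <- as_weight_matrix(W, threshold)
  ci <- onnela_clustering_cpp(W)
  names(ci) <- rownames(W)
  m <- if (all(is.na(ci))) 0 else mean(ci, na.rm = TRUE)
  list(node = ci, mean = m)
}

#' Characteristic (shortest) path length
#'
#' Mean weighted shortest-path distance over ordered node pairs, with edge
#' lengths d = 1/w. Unreachable pairs are excluded from the mean and
#' counted in the `n_unreachable` attribute.
#'
#' @inheritParams weighted_clustering
#' @return The mean shortest path length (scalar).
#' @export
shortest_path_length <- function(W, threshold = 0) {
  W <- as_weight_matrix(W, threshold)
  if (all(W == 0)) abort_degenerate("all-zero weight matrix has no paths.")
  st <- path_stats_cpp(W)
  structure(st[["L"]], n_unreachable = as.integer(st[["n_unreachable"]]))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs
#' (unreachable pairs contribute 0); equals 1 for a complete unit-weight
#' graph.
#'
#' @inheritParams weighted_clustering
#' @return Efficiency in \[0, 1\] for weights in \[0, 1\].
#' @export
global_efficiency <- function(W, threshold = 0) {
  W <- as_weight_matrix(W, threshold)
  unname(path_stats_cpp(W)[["eglob"]])
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on
#' each node's neighbours (the node itself removed); nodes with fewer than
#' two neighbours contribute 0.
#'
#' @inheritParams weighted_clustering
#' @return Local efficiency (scalar).
#' @export
local_efficiency <- function(W, threshold = 0) {
  W <- as_weight_matrix(W, threshold)
  local_efficiency_cpp(W)
}

#' Null-model configuration for the small-world index
#'
#' @param n_surrogates Number of random surrogates (>= 20, default 100).
#' @param scheme Only `"weight_permutation"`: off-diagonal upper-triangle
#'   weights permuted uniformly at random, then symmetrised.
#' @param seed RNG seed making the ensemble deterministic.
#' @return A `null_model_config` object.
#' @export
null_model_config <- function(n_surrogates = 100, scheme = "weight_permutation",
                              seed = 1L) {
  if (n_surrogates < 20) abort_value("`n_surrogates` must be >= 20.")
  scheme <- match.arg(scheme, "weight_permutation")
  structure(list(n_surrogates = as.integer(n_surrogates), scheme = scheme,
                 seed = as.integer(seed)),
            class = "null_model_config")
}

null_permutations <- function(n_nodes, null) {
  m <- n_nodes * (n_nodes - 1) / 2
  withr::with_seed(null$seed,
    vapply(seq_len(null$n_surrogates), function(i) sample.int(m), integer(m)))
}

#' Small-world index against a weight-permutation null
#'
#' sigma = (C / C_rand) / (L / L_rand), where C_rand and L_rand are the
#' means of clustering and path length over the null ensemble. Values
#' above 1 indicate small-world organisation (more clustered than random
#' at comparable path length).
#'
#' @inheritParams weighted_clustering
#' @param null A [null_model_config()].
#' @return sigma (scalar), deterministic given the null seed.
#' @export
small_world_index <- function(W, null = null_model_config(), threshold = 0) {
  W <- as_weight_matrix(W, threshold)
  if (all(W == 0)) abort_degenerate("all-zero weight matrix.")
  C <- weighted_clustering(W)$mean
  L <- as.numeric(shortest_path_length(W))
  perms <- null_permutations(nrow(W), null)
  stats <- null_ensemble_stats_cpp(W, perms)
  C_rand <- mean(stats[, "C"])
  L_rand <- mean(stats[, "L"])
  if (!is.finite(C_rand) || !is.finite(L_rand) || C_rand == 0 || L_rand == 0) {
    abort_degenerate("degenerate null ensemble (C_rand or L_rand is 0).")
  }
  (C / C_rand) / (L / L_rand)
}

#' All five network metrics of one weighted matrix
#'
#' Convenience aggregation of clustering coefficient, characteristic path
#' length, global and local efficiency, and the small-world index.
#'
#' @inheritParams small_world_index
#' @param band,state,subject_id,epoch Optional metadata carried into the
#'   output (taken from `W` when it is a [plv_matrix()]).
#' @return One-row tibble with columns `subject_id`, `state`, `band`,
#'   `epoch`, `clustering_coefficient`, `shortest_path_length`,
#'   `global_efficiency`, `local_efficiency`, `small_world_index`.
#' @export
metrics_bundle <- function(W, null = null_model_config(), threshold = 0,
                           band = NA_character_, state = NA_character_,
                           subject_id = NA_character_, epoch = NA_character_) {
  if (inherits(W, "plv_matrix")) {
    band <- W$band
    state <- W$state
    subject_id <- W$subject_id
    epoch <- as.character(W$epoch_index)
  }
  Wm <- as_weight_matrix(W, threshold)
  tibble(
    subject_id = subject_id, state = state, band = band, epoch = epoch,
    clustering_coefficient = weighted_clustering(Wm)$mean,
    shortest_path_length = as.numeric(shortest_path_length(Wm)),
    global_efficiency = global_efficiency(Wm),
    local_efficiency = local_efficiency(Wm),
    small_world_index = small_world_index(Wm, null))
}

metric_columns <- function() {
  c("clustering_coefficient", "shortest_path_length", "global_efficiency",
    "local_efficiency", "small_world_index")
}
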