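# Fixtures and independent brute-force oracles used across the suite.

# Random toy layer: symmetric thresholded weights over n nodes.
random_layer <- function(n, seed, density = 0.6, threshold = 0.3,
                         subject_id = "toy") {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    on <- runif(length(up)) < density
    W[up[on]] <- runif(sum(on), threshold, 1)
    W <- W + t(W)
  })
  structure(list(subject_id = subject_id, weights = W, node_ids = seq_len(n)),
            class = "layer_network")
}

# Naive double-loop nodal metrics, independent of the package's vectorised
# implementation.
oracle_layer_metrics <- function(W) {
  n <- nrow(W)
  k <- s <- y <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (W[i, j] > 0) k[i] <- k[i] + 1
      s[i] <- s[i] + W[i, j]
    }
  }
  for (i in seq_len(n)) {
    if (s[i] > 0) for (j in seq_len(n)) y[i] <- y[i] + (W[i, j] / s[i])^2
  }
  s_cond <- y_cond <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(k == k[i])
    s_cond[i] <- mean(s[same])
    y_cond[i] <- mean(y[same])
  }
  list(k = k, s = s, y = y, s_cond = s_cond, y_cond = y_cond)
}

# Multiplex degree by explicit union of edge lists.
oracle_k_multi <- function(layers) {
  n <- nrow(layers[[1]]$weights)
  pairs <- unique(do.call(rbind, lapply(layers, function(l) {
    which(l$weights > 0, arr.ind = TRUE)
  })))
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- length(unique(pairs[pairs[, 1] == i, 2]))
  k
}

# Brute-force near-cubic factorisation of V (ordered triples, min aspect
# ratio, lexicographic tie-break).
oracle_patch_shape <- function(V) {
  best <- NULL
  for (dx in seq_len(V)) {
    if (V %% dx) next
    for (dy in seq_len(V %/% dx)) {
      if ((V %/% dx) %% dy) next
      dz <- V %/% (dx * dy)
      cand <- c(dx, dy, dz, max(dx, dy, dz) / min(dx, dy, dz))
      if (is.null(best) || cand[4] < best[4] ||
          (cand[4] == best[4] &&
           (cand[1] < best[1] || (cand[1] == best[1] && cand[2] < best[2])))) {
        best <- cand
      }
    }
  }
  best[1:3]
}

# Small cohort spec used by several module tests (cheap: 18^3 volumes).
toy_spec <- function(effect_magnitude = 0, seed = 1, n_control = 3,
                     n_case = 3, effect_patches = integer(0),
                     effect_kind = "decorrelate", noise_sd = 0.5) {
  cohort_spec(c(18, 18, 18), "full", n_control = n_control, n_case = n_case,
              patch_shape = c(6, 6, 6), effect_patches = effect_patches,
              effect_kind = effect_kind, effect_magnitude = effect_magnitude,
              noise_sd = noise_sd, seed = seed)
}
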