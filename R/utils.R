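# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so package functions never perturb user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed for unit `index` of a parent seed; keeps the
# result a positive 32-bit integer so it is portable across platforms.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 1e6) * 1009 + as.double(index) * 104729 + 17
  as.integer(s %% 2147483587) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Gaussian separable smoothing of a 3D array. `periodic = TRUE` wraps at the
# boundaries (used to build seamless texture tiles), otherwise the kernel is
# renormalised at the edges.
smooth3d <- function(arr, sigma = 2, periodic = FALSE) {
  stopifnot(length(dim(arr)) == 3)
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  k <- exp(-(offs^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    # Dense n x n convolution matrix: cheap at phantom scale.
    K <- matrix(0, n, n)
    for (j in seq_along(offs)) {
      idx <- seq_len(n) + offs[j]
      if (periodic) {
        idx <- ((idx - 1) %% n) + 1
        K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + k[j]
      } else {
        ok <- idx >= 1 & idx <= n
        K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + k[j]
      }
    }
    if (!periodic) K <- K / rowSums(K)
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = d[axis])
    dim(m) <- d[perm]
    aperm(m, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}
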