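# Per-subject weighted networks (multiplex layers) from absolute Pearson
# correlations between patch intensity vectors, and their assembly into a
# cohort multiplex network on the shared node set.

#' Extract a patch intensity vector
#'
#' Flattens the voxels of one grid box in a fixed axis order (x fastest, then
#' y, then z) so vectors from different subjects are aligned voxelwise.
#'
#' @param volume 3D intensity array.
#' @param box One row of `grid$boxes` (0-based half-open intervals).
#' @return Numeric vector of length V.
#' @export
patch_vector <- function(volume, box) {
  as.vector(volume[(box$x0 + 1):box$x1, (box$y0 + 1):box$y1,
                   (box$z0 + 1):box$z1])
}

#' Correlation weight of one patch pair
#'
#' The link weight is the absolute Pearson correlation of the two intensity
#' vectors, with correlations below the threshold discarded as noise:
#' `|r|` if `|r| >= threshold`, else 0. A patch with zero variance has no
#' defined correlation and yields weight 0 (no link). The thresholding is
#' strict on "lower than": `|r|` exactly at the threshold is kept.
#'
#' @param u,v Numeric vectors of equal length (>= 3).
#' @param threshold Correlation magnitude below which links are discarded
#'   (default 0.3).
#' @return A scalar weight in `{0} U [threshold, 1]`.
#' @export
#' @examples
#' edge_weight(c(1, 2, 3, 4), c(4, 3, 2, 1))  # 1.0
edge_weight <- function(u, v, threshold = 0.3) {
  if (length(u) != length(v)) {
    stop("patch vectors differ in length (", length(u), " vs ", length(v),
         ")", call. = FALSE)
  }
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  r <- abs(stats::cor(u, v))
  if (r >= threshold) r else 0
}

#' Build one subject's layer network
#'
#' Computes the full matrix of absolute Pearson correlations between all
#' valid-patch intensity vectors, thresholded as in [edge_weight()]. The
#' result is a symmetric weighted adjacency with zero diagonal over the
#' grid's valid nodes; node identity (the grid box index) is shared across
#' subjects, which is what makes the layers stackable into a multiplex.
#'
#' @param volume 3D intensity array in the shared space.
#' @param grid A `patch_grid` with validity computed ([apply_mask()]).
#' @param threshold Correlation threshold (default 0.3).
#' @param subject_id Optional id stored with the layer.
#' @return An object of class `layer_network`: `subject_id`, `weights`
#'   (N x N), `node_ids` (valid box indices).
#' @export
build_layer <- function(volume, grid, threshold = 0.3, subject_id = NA) {
  stopifnot(inherits(grid, "patch_grid"))
  if (is.na(grid$n_nodes)) {
    stop("grid validity not computed; call apply_mask() first", call. = FALSE)
  }
  if (grid$n_nodes < 2) stop("need at least 2 valid nodes", call. = FALSE)
  boxes <- grid$boxes[grid$boxes$valid, ]
  X <- vapply(seq_len(nrow(boxes)), function(i) patch_vector(volume, boxes[i, ]),
              numeric(grid$shape$V))
  sds <- apply(X, 2, stats::sd)
  C <- suppressWarnings(abs(stats::cor(X)))
  C[sds == 0, ] <- 0
  C[, sds == 0] <- 0
  C[C < threshold] <- 0
  diag(C) <- 0
  dimnames(C) <- NULL
  structure(list(subject_id = subject_id, weights = C,
                 node_ids = boxes$box),
            class = "layer_network")
}

#' @export
print.layer_network <- function(x, ...) {
  n <- length(x$node_ids)
  cat("<layer_network> subject ", as.character(x$subject_id), ": ", n,
      " nodes, ", sum(x$weights > 0) / 2, " links\n", sep = "")
  invisible(x)
}

#' Assemble layers into a multiplex network
#'
#' Stacks the subjects' layers on the shared node set and computes the
#' multiplex degree: `a_multi[i, j]` is 1 when at least one layer links nodes
#' i and j, and `k_multi[i] = sum_j a_multi[i, j]` counts a node's distinct
#' partners across the whole cohort.
#'
#' @param layers List of `layer_network` objects sharing `node_ids`.
#' @return An object of class `multiplex_network`: `layers`, `a_multi`,
#'   `k_multi`, `node_ids`.
#' @export
assemble_multiplex <- function(layers) {
  stopifnot(length(layers) >= 1)
  ids <- layers[[1]]$node_ids
  for (l in layers) {
    if (!identical(l$node_ids, ids)) {
      stop("layers do not share the same node set", call. = FALSE)
    }
  }
  A <- Reduce(`|`, lapply(layers, function(l) l$weights > 0))
  A <- matrix(as.integer(A), nrow = length(ids))
  structure(list(layers = layers, a_multi = A, k_multi = rowSums(A),
                 node_ids = ids),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("<multiplex_network> ", length(x$layers), " layers on ",
      length(x$node_ids), " shared nodes; multiplex degree range [",
      min(x$k_multi), ", ", max(x$k_multi), "]\n", sep = "")
  invisible(x)
}

#' Export a layer as a weighted edge list
#'
#' @param layer A `layer_network`.
#' @param path Output TSV (`node_i`, `node_j`, `weight`), upper triangle only.
#' @return `path`, invisibly.
#' @export
write_layer_edges <- function(layer, path) {
  idx <- which(upper.tri(layer$weights) & layer$weights > 0, arr.ind = TRUE)
  df <- tibble::tibble(node_i = layer$node_ids[idx[, 1]],
                       node_j = layer$node_ids[idx[, 2]],
                       weight = layer$weights[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
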