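# Nodal network metrics — four single-layer and four multiplex — and the
# subjects x 8N feature matrix with its pre-classification filtering.
#
# Single layer, per node i of layer alpha:
#   strength        s_i = sum_j w_ij
#   inv. part. ratio y_i = sum_j (w_ij / s_i)^2   (1/y_i in [1, k_i])
#   conditional means s(k), Y(k): means of s and y over nodes of degree k.
# Multiplex, weighing the layer metrics on the multiplex degree k_multi:
#   multiS_i = s_i * k_multi_i / (N - 1),  multiY_i likewise;
#   multiSc, multiYc: means of s and y over nodes sharing k_multi.

metric_order <- c("S", "Y", "Sc", "Yc", "multiS", "multiY", "multiSc", "multiYc")

#' Single-layer nodal metrics
#'
#' Computes, for every node of one layer, the degree, strength, inverse
#' participation ratio, and the degree-conditional means of strength and IPR
#' (the mean over all nodes sharing the node's degree). Strength measures a
#' node's total connectivity; the reciprocal of the IPR, between 1 and the
#' degree, measures how evenly that connectivity is spread over the node's
#' links (equal to the degree for uniform weights, near 1 when one link
#' dominates). Isolated nodes (strength 0) get IPR 0 by convention.
#'
#' @param layer A `layer_network`.
#' @return A tibble with columns `node`, `degree`, `strength`, `ipr`,
#'   `strength_cond`, `ipr_cond`.
#' @export
layer_features <- function(layer) {
  W <- layer$weights
  k <- rowSums(W > 0)
  s <- rowSums(W)
  y <- ifelse(s > 0, rowSums((W / ifelse(s > 0, s, 1))^2), 0)
  tibble::tibble(node = layer$node_ids, degree = as.integer(k), strength = s,
                 ipr = y,
                 strength_cond = stats::ave(s, k),
                 ipr_cond = stats::ave(y, k))
}

#' Multiplex nodal metrics for one layer
#'
#' Weighs the single-layer metrics on the multiplex degree: the nodal
#' variants scale strength and IPR by the normalised multiplex degree
#' `k_multi / (N - 1)` (so they reduce to the single-layer metrics when the
#' multiplex is complete and vanish for multiplex-isolated nodes); the
#' conditional variants are the means of strength and IPR over nodes sharing
#' the same multiplex degree.
#'
#' @param lf Tibble from [layer_features()].
#' @param k_multi Integer vector of multiplex degrees aligned to `lf$node`.
#' @return `lf` with columns `multi_strength`, `multi_ipr`,
#'   `multi_strength_cond`, `multi_ipr_cond` appended.
#' @export
multiplex_node_features <- function(lf, k_multi) {
  n <- nrow(lf)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  stopifnot(length(k_multi) == n)
  w <- k_multi / (n - 1)
  lf$multi_strength <- lf$strength * w
  lf$multi_ipr <- lf$ipr * w
  lf$multi_strength_cond <- stats::ave(lf$strength, k_multi)
  lf$multi_ipr_cond <- stats::ave(lf$ipr, k_multi)
  lf
}

feature_colnames <- function(node_ids) {
  width <- max(3, nchar(max(node_ids)))
  unlist(lapply(metric_order,
                function(m) sprintf("%s_n%0*d", m, width, node_ids)))
}

#' Parse feature names into metric and node
#'
#' @param feature Character vector of names like `"multiS_n012"`.
#' @return Tibble with columns `feature`, `metric`, `node`.
#' @export
parse_feature_names <- function(feature) {
  m <- regmatches(feature, regexec("^([A-Za-z]+)_n([0-9]+)$", feature))
  tibble::tibble(feature = feature,
                 metric = vapply(m, `[`, character(1), 2),
                 node = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Assemble the subjects x 8N feature matrix
#'
#' One row per subject; eight blocks of N columns, one block per metric in
#' the order S, Y, Sc, Yc, multiS, multiY, multiSc, multiYc, with column
#' names `<metric>_n<node>`. The node index is the grid box index, shared by
#' all subjects, so a column always refers to one fixed patch of the
#' registered space.
#'
#' @param multiplex A `multiplex_network`.
#' @return A tibble of class `patchplex_features` with a `subject_id` column
#'   followed by the 8N feature columns; attribute `dropped` is an empty
#'   provenance tibble filled by [filter_features()].
#' @export
build_feature_matrix <- function(multiplex) {
  stopifnot(inherits(multiplex, "multiplex_network"))
  if (length(multiplex$layers) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  rows <- lapply(multiplex$layers, function(layer) {
    lf <- multiplex_node_features(layer_features(layer), multiplex$k_multi)
    c(lf$strength, lf$ipr, lf$strength_cond, lf$ipr_cond,
      lf$multi_strength, lf$multi_ipr, lf$multi_strength_cond,
      lf$multi_ipr_cond)
  })
  values <- do.call(rbind, rows)
  colnames(values) <- feature_colnames(multiplex$node_ids)
  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(
    out,
    subject_id = vapply(multiplex$layers,
                        function(l) as.character(l$subject_id), character(1)),
    .before = 1)
  new_patchplex_features(out, dropped = tibble::tibble(
    feature = character(0), reason = character(0), partner = character(0)))
}

new_patchplex_features <- function(df, dropped) {
  structure(df, dropped = dropped,
            class = c("patchplex_features", class(tibble::tibble())))
}

#' Dropped-feature provenance
#'
#' @param x A `patchplex_features` tibble.
#' @return Tibble `feature`, `reason` (`null_mean_variance` or
#'   `high_correlation`), `partner` (for correlation drops, the retained
#'   feature).
#' @export
dropped_features <- function(x) attr(x, "dropped")

#' Filter constant and highly correlated features
#'
#' Pre-classification cleanup: first removes features with null mean and
#' variance (constant columns carry no information and zero-variance columns
#' break correlation screening), then scans feature pairs in column order and
#' drops the later feature of any pair whose Pearson correlation exceeds
#' `corr_threshold`, recording which retained feature it duplicated. The scan
#' is greedy against the already-kept set, so the first feature of a
#' correlated group survives; applying the filter twice is a no-op.
#'
#' @param x A `patchplex_features` tibble.
#' @param corr_threshold Correlation above which the later feature is dropped
#'   (default 0.95, strict).
#' @return The filtered `patchplex_features` tibble; `dropped_features()`
#'   lists every removal with its reason.
#' @export
filter_features <- function(x, corr_threshold = 0.95) {
  stopifnot(inherits(x, "patchplex_features"))
  if (nrow(x) < 3) stop("need at least 3 subjects to filter", call. = FALSE)
  feats <- setdiff(names(x), "subject_id")
  X <- as.matrix(as.data.frame(x)[feats])
  v <- apply(X, 2, stats::var)
  mu <- colMeans(X)
  const <- v == 0 | (abs(mu) < 1e-300 & v < 1e-300)
  dropped <- tibble::tibble(feature = feats[const],
                            reason = "null_mean_variance",
                            partner = NA_character_)
  feats2 <- feats[!const]
  if (length(feats2) == 0) stop("all features dropped", call. = FALSE)
  C <- suppressWarnings(stats::cor(X[, feats2, drop = FALSE]))
  kept <- integer(0)
  for (j in seq_along(feats2)) {
    hit <- kept[which(C[kept, j] > corr_threshold)[1]]
    if (length(kept) && !is.na(hit)) {
      dropped <- tibble::add_row(dropped, feature = feats2[j],
                                 reason = "high_correlation",
                                 partner = feats2[hit])
    } else {
      kept <- c(kept, j)
    }
  }
  if (length(kept) == 0) stop("all features dropped", call. = FALSE)
  out <- x[, c("subject_id", feats2[kept])]
  prev <- attr(x, "dropped")
  new_patchplex_features(out, dropped = rbind(prev, dropped))
}

#' Write a feature matrix to CSV with a provenance sidecar
#'
#' @param x A `patchplex_features` tibble.
#' @param path Output CSV; the dropped-feature record goes to
#'   `<path>.dropped.json`.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(dropped_features(x), paste0(path, ".dropped.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
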