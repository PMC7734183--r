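# Stability assessment of the selected features: which features were chosen
# across cross-validation rounds more often than the selection mechanism's
# chance rate, which patches they sit on, and which anatomical regions those
# patches overlap.

#' One-sided proportion test of a selection count
#'
#' Tests whether a feature's selection frequency over the rounds exceeds the
#' chance rate `p0`, with the standard test of equal or given proportions
#' (chi-square with continuity correction, one-sided "greater").
#'
#' @param count Rounds in which the feature was selected.
#' @param rounds Total rounds (> 0).
#' @param p0 Null selection probability. The default 0.25 is the chance rate
#'   the third-quartile selection rule induces (a quarter of features exceeds
#'   Q3 each round under exchangeability).
#' @return The p-value.
#' @export
proportion_test <- function(count, rounds, p0 = 0.25) {
  if (rounds <= 0) stop("rounds must be positive", call. = FALSE)
  stopifnot(count >= 0, count <= rounds, p0 > 0, p0 < 1)
  suppressWarnings(
    stats::prop.test(count, rounds, p = p0, alternative = "greater",
                     correct = TRUE)$p.value)
}

#' Features selected more often than chance
#'
#' Applies [proportion_test()] to every feature's selection count and flags
#' significance at the Bonferroni-corrected level `alpha / n_nodes` (the
#' correction divides by the node count N).
#'
#' @param counts Tibble with columns `feature` and `count` (e.g.
#'   `cv_result$selection_counts`).
#' @param rounds Total cross-validation rounds.
#' @param n_nodes Number of network nodes N used as the Bonferroni divisor.
#' @param alpha Family-wise level (default 0.05).
#' @param p0 Null selection probability (default 0.25).
#' @return The tibble with `p_value` and `significant` columns appended,
#'   sorted by decreasing count.
#' @export
significant_features <- function(counts, rounds, n_nodes, alpha = 0.05,
                                 p0 = 0.25) {
  stopifnot(n_nodes >= 1)
  thr <- alpha / n_nodes
  out <- dplyr::mutate(
    counts,
    p_value = vapply(.data$count, proportion_test, numeric(1),
                     rounds = rounds, p0 = p0),
    significant = .data$p_value < thr)
  dplyr::arrange(out, dplyr::desc(.data$count))
}

#' Anatomical regions overlapping one patch
#'
#' Reports the labelled regions occupying strictly more than `min_fraction`
#' of the patch volume, sorted by overlap fraction (code 0 is unlabeled and
#' ignored).
#'
#' @param box One row of `grid$boxes`.
#' @param label_volume A `label_volume`.
#' @param min_fraction Minimum overlap fraction (default 0.10, strict).
#' @return Tibble `region_name`, `code`, `fraction`.
#' @export
map_patch_regions <- function(box, label_volume, min_fraction = 0.10) {
  stopifnot(inherits(label_volume, "label_volume"))
  sl <- label_volume$data[(box$x0 + 1):box$x1, (box$y0 + 1):box$y1,
                          (box$z0 + 1):box$z1]
  tab <- table(sl[sl != 0])
  frac <- as.numeric(tab) / length(sl)
  keep <- frac > min_fraction
  codes <- as.integer(names(tab))[keep]
  out <- tibble::tibble(
    code = codes,
    fraction = frac[keep],
    region_name = label_volume$lut$region_name[
      match(codes, label_volume$lut$code)])
  dplyr::arrange(out[c("region_name", "code", "fraction")],
                 dplyr::desc(.data$fraction))
}

#' Assess which features and patches drive the discrimination
#'
#' Runs the proportion test on every feature's selection count, maps each
#' feature to its patch (node), and — when a label volume is supplied — each
#' significant patch to the anatomical regions covering more than 10% of it.
#'
#' @param cv A `cv_result`.
#' @param grid The `patch_grid` the features were computed on.
#' @param alpha Family-wise level (default 0.05); Bonferroni divisor is the
#'   grid's node count.
#' @param p0 Null selection probability (default 0.25).
#' @param label_volume Optional `label_volume` for region naming.
#' @param features Optional filtered `patchplex_features` the CV ran on.
#'   When given, its dropped-feature provenance extends the significant node
#'   set: a patch whose feature was removed by the correlation filter as a
#'   duplicate of a significant retained feature carries the same
#'   information, so it is flagged too (the filter collapses redundant
#'   patches; without this, only the first patch of a redundant group could
#'   ever be identified).
#' @return An object of class `assessment`: tibble `features` (feature,
#'   metric, node, count, p_value, significant), `significant_nodes`
#'   (integer; includes duplicate-covered patches when `features` is given),
#'   and `regions` (tibble node, region_name, code, fraction; empty without
#'   a label volume).
#' @export
assess_features <- function(cv, grid, alpha = 0.05, p0 = 0.25,
                            label_volume = NULL, features = NULL) {
  stopifnot(inherits(cv, "cv_result"), inherits(grid, "patch_grid"))
  rounds <- nrow(cv$rounds)
  res <- significant_features(cv$selection_counts, rounds,
                              n_nodes = grid$n_nodes, alpha = alpha, p0 = p0)
  parsed <- parse_feature_names(res$feature)
  res$metric <- parsed$metric[match(res$feature, parsed$feature)]
  res$node <- parsed$node[match(res$feature, parsed$feature)]
  res <- res[c("feature", "metric", "node", "count", "p_value", "significant")]
  sig_nodes <- sort(unique(res$node[res$significant]))
  if (!is.null(features)) {
    sig_feats <- res$feature[res$significant]
    d <- dropped_features(features)
    covered <- d$feature[d$reason == "high_correlation" &
                           d$partner %in% sig_feats]
    if (length(covered)) {
      sig_nodes <- sort(unique(c(sig_nodes,
                                 parse_feature_names(covered)$node)))
    }
  }
  regions <- tibble::tibble(node = integer(0), region_name = character(0),
                            code = integer(0), fraction = numeric(0))
  if (!is.null(label_volume) && length(sig_nodes)) {
    regions <- purrr::map_dfr(sig_nodes, function(nd) {
      box <- grid$boxes[grid$boxes$box == nd, ]
      r <- map_patch_regions(box, label_volume)
      if (nrow(r)) tibble::add_column(r, node = nd, .before = 1) else NULL
    })
  }
  structure(list(features = res, significant_nodes = sig_nodes,
                 regions = regions, alpha = alpha, p0 = p0, rounds = rounds,
                 n_nodes = grid$n_nodes),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat("<assessment> ", nrow(x$features), " features over ", x$rounds,
      " rounds; ", sum(x$features$significant),
      " significant at p < ", signif(x$alpha / x$n_nodes, 3), " (alpha ",
      x$alpha, " / ", x$n_nodes, " nodes), on ",
      length(x$significant_nodes), " patch(es)\n", sep = "")
  invisible(x)
}

#' Write an assessment report
#'
#' @param x An `assessment`.
#' @param path Output CSV of the per-feature table; the region report goes to
#'   `<path>.regions.json`.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(x, path) {
  utils::write.csv(x$features, path, row.names = FALSE)
  jsonlite::write_json(x$regions, paste0(path, ".regions.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binary NIfTI mask of the significant patches
#'
#' @param x An `assessment`.
#' @param grid The `patch_grid`.
#' @param path Output NIfTI file.
#' @return `path`, invisibly.
#' @export
write_significant_mask <- function(x, grid, path) {
  m <- array(0, grid$volume_shape)
  for (nd in x$significant_nodes) {
    b <- grid$boxes[grid$boxes$box == nd, ]
    m[(b$x0 + 1):b$x1, (b$y0 + 1):b$y1, (b$z0 + 1):b$z1] <- 1
  }
  RNifti::writeNifti(m, path)
  invisible(path)
}
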