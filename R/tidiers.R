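# broom-style tidiers and ggplot2 visualisations for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per feature with its selection count and frequency across rounds.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble `feature`, `metric`, `node`, `count`, `frequency`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  parsed <- parse_feature_names(x$selection_counts$feature)
  dplyr::arrange(
    tibble::tibble(feature = x$selection_counts$feature,
                   metric = parsed$metric, node = parsed$node,
                   count = x$selection_counts$count,
                   frequency = x$selection_counts$count / nrow(x$rounds)),
    dplyr::desc(.data$count))
}

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble with metric means and SDs, the Wilson interval
#'   of the mean accuracy, and the round count.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  sm <- x$summary
  g <- function(m, col) sm[[col]][sm$metric == m]
  tibble::tibble(
    accuracy = g("accuracy", "mean"), accuracy_sd = g("accuracy", "sd"),
    specificity = g("specificity", "mean"),
    specificity_sd = g("specificity", "sd"),
    sensitivity = g("sensitivity", "mean"),
    sensitivity_sd = g("sensitivity", "sd"),
    auc = g("auc", "mean"), auc_sd = g("auc", "sd"),
    wilson_lo = unname(x$wilson["lo"]), wilson_hi = unname(x$wilson["hi"]),
    rounds = nrow(x$rounds))
}

#' Tidy an assessment
#'
#' @param x An `assessment`.
#' @param ... Unused.
#' @return The per-feature tibble (feature, metric, node, count, p_value,
#'   significant).
#' @method tidy assessment
#' @export
tidy.assessment <- function(x, ...) x$features

#' One-row summary of an assessment
#'
#' @param x An `assessment`.
#' @param ... Unused.
#' @return A one-row tibble: features tested, Bonferroni threshold,
#'   significant features and patches.
#' @method glance assessment
#' @export
glance.assessment <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$features),
                 bonferroni_threshold = x$alpha / x$n_nodes,
                 n_significant = sum(x$features$significant),
                 n_significant_patches = length(x$significant_nodes),
                 rounds = x$rounds)
}

#' Tidy a scale sweep
#'
#' @param x A `scale_sweep`.
#' @param ... Unused.
#' @return The cross-scale summary tibble.
#' @method tidy scale_sweep
#' @export
tidy.scale_sweep <- function(x, ...) x$summary

#' Distribution of validation metrics over rounds
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot: one violin/box per metric.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$rounds[c("accuracy", "specificity", "sensitivity", "auc")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "validation metric",
                  title = "Cross-validation metrics over rounds") +
    ggplot2::ylim(0, 1)
}

#' Mean selection frequency per network metric
#'
#' Shows which of the eight nodal metrics contribute most to the
#' discrimination (mean fraction of that metric's features selected per
#' round).
#'
#' @param cv A `cv_result`.
#' @return A ggplot bar chart.
#' @export
plot_metric_selection <- function(cv) {
  td <- tidy(cv)
  agg <- dplyr::summarise(dplyr::group_by(td, .data$metric),
                          mean_frequency = mean(.data$frequency),
                          .groups = "drop")
  agg$metric <- factor(agg$metric, levels = metric_order)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$metric,
                                    y = .data$mean_frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean selection frequency",
                  title = "Feature selection by network metric")
}

#' Accuracy and AUC against patch volume
#'
#' @param object A `scale_sweep`.
#' @param ... Unused.
#' @return A ggplot: mean +/- SD of accuracy and AUC per scale.
#' @method autoplot scale_sweep
#' @export
autoplot.scale_sweep <- function(object, ...) {
  sm <- object$summary
  long <- tibble::tibble(
    V = rep(sm$V, 2),
    metric = rep(c("accuracy", "auc"), each = nrow(sm)),
    mean = c(sm$accuracy, sm$auc),
    sd = c(sm$accuracy_sd, sm$auc_sd))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$V), y = .data$mean,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "patch volume V (voxels)", y = "mean over CV rounds",
                  title = "Classification performance by patch scale") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
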