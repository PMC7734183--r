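# Repeated stratified cross-validation with nested random-forest feature
# selection. Each round draws a balanced subsample, splits it 80/20, selects
# the features whose permutation importance exceeds the third quartile on the
# training part only, trains a second forest on those features, and scores
# the held-out part. Metrics are averaged over rounds and the mean accuracy
# gets a Wilson score interval; per-feature selection counts feed the
# stability assessment.

#' Cross-validation configuration
#'
#' @param rounds Number of cross-validation rounds (default 1000).
#' @param train_fraction Fraction of each balanced class used for training
#'   (default 0.8).
#' @param n_trees Trees per forest (default 500); each tree draws
#'   `floor(sqrt(p))` candidate features per split.
#' @param importance_quantile Quantile of the importance distribution a
#'   feature must strictly exceed to be selected (default 0.75).
#' @param seed Master seed; every round's subsampling, forest growing and
#'   permutation importance derive from it.
#' @param positive_class Label of the case (seizure-affected) class
#'   (default 1).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(rounds = 1000, train_fraction = 0.8, n_trees = 500,
                      importance_quantile = 0.75, seed = 1,
                      positive_class = 1) {
  stopifnot(rounds >= 1, train_fraction > 0, train_fraction < 1, n_trees >= 1)
  structure(list(rounds = as.integer(rounds),
                 train_fraction = train_fraction, n_trees = as.integer(n_trees),
                 importance_quantile = importance_quantile,
                 seed = as.integer(seed), positive_class = positive_class),
            class = "cv_config")
}

#' Balanced stratified train/validation split for one round
#'
#' Undersamples the majority class (without replacement) to the minority
#' class size so the round works on a balanced set, then splits each class
#' `train_fraction`/rest with per-class training counts rounded to nearest
#' and at least one validation subject per class.
#'
#' @param labels Vector of 0/1 class labels.
#' @param seed Integer seed for this round.
#' @param train_fraction Training fraction (default 0.8).
#' @return List with integer index vectors `train_ids` and `validation_ids`
#'   (disjoint).
#' @export
stratify_round <- function(labels, seed, train_fraction = 0.8) {
  idx0 <- which(labels == 0)
  idx1 <- which(labels == 1)
  m <- min(length(idx0), length(idx1))
  if (m < 5) {
    stop("smallest class has ", m, " subjects; need at least 5 for a ",
         "nonempty stratified validation set", call. = FALSE)
  }
  n_train <- round(train_fraction * m)
  if (n_train >= m) n_train <- m - 1
  if (n_train < 1) stop("training set would be empty", call. = FALSE)
  with_seed(seed, {
    take0 <- sample(idx0, m)
    take1 <- sample(idx1, m)
    list(train_ids = sort(c(take0[seq_len(n_train)],
                            take1[seq_len(n_train)])),
         validation_ids = sort(c(take0[(n_train + 1):m],
                                 take1[(n_train + 1):m])))
  })
}

fit_forest <- function(x, y, config, seed, importance = "none",
                       probability = FALSE) {
  ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                 num.trees = config$n_trees,
                 mtry = max(1L, floor(sqrt(ncol(x)))),
                 importance = importance, probability = probability,
                 seed = seed, num.threads = 1)
}

#' Select features by nested random-forest importance
#'
#' Fits a forest on the training rows only and returns the features whose
#' out-of-bag permutation importance (mean decrease in accuracy) strictly
#' exceeds the third quartile of the importance distribution (linear
#' interpolation between order statistics). If every importance is equal the
#' cut is empty and the full feature set is returned with a warning.
#'
#' @param train_x Data frame / matrix of training feature rows.
#' @param train_y Training labels (0/1).
#' @param config A [cv_config()].
#' @param seed Seed for forest growing and the importance permutations.
#' @return Character vector of selected feature names.
#' @export
select_important <- function(train_x, train_y, config, seed = config$seed) {
  train_x <- as.data.frame(train_x)
  if (ncol(train_x) < 2) stop("need at least 2 features", call. = FALSE)
  fit <- fit_forest(train_x, train_y, config, seed, importance = "permutation")
  imp <- ranger::importance(fit)
  # features that are constant on this training subsample have no defined
  # permutation importance; treat as zero
  imp[!is.finite(imp)] <- 0
  q3 <- stats::quantile(imp, config$importance_quantile, names = FALSE,
                        type = 7)
  sel <- names(imp)[imp > q3]
  if (length(sel) == 0) {
    warning("importance distribution is degenerate; keeping all features",
            call. = FALSE)
    sel <- names(imp)
  }
  sel
}

#' Train on selected features and score the validation set
#'
#' Fits the second forest on the selected features of the training rows and
#' evaluates the held-out rows: class predictions at the 0.5 probability
#' cutoff give accuracy, sensitivity (recall of the case class) and
#' specificity (recall of the control class); the AUC is computed from the
#' predicted case-class probabilities.
#'
#' @param train_x,train_y Training features and labels.
#' @param val_x,val_y Validation features and labels (both classes present).
#' @param selected Character vector of feature names to use.
#' @param config A [cv_config()].
#' @param seed Seed for forest growing.
#' @return One-row tibble: `accuracy`, `specificity`, `sensitivity`, `auc`,
#'   `n_validation`.
#' @export
train_and_eval <- function(train_x, train_y, val_x, val_y, selected, config,
                           seed = config$seed) {
  stopifnot(length(selected) >= 1)
  if (length(unique(val_y)) < 2) {
    stop("validation set contains a single class", call. = FALSE)
  }
  train_x <- as.data.frame(train_x)[selected]
  val_x <- as.data.frame(val_x)[selected]
  fit <- fit_forest(train_x, train_y, config, seed, probability = TRUE)
  prob <- stats::predict(fit, data = val_x)$predictions[, "1"]
  pred <- as.integer(prob >= 0.5)
  pos <- val_y == 1
  tibble::tibble(
    accuracy = mean(pred == val_y),
    specificity = mean(pred[!pos] == 0),
    sensitivity = mean(pred[pos] == 1),
    auc = as.numeric(pROC::auc(response = val_y, predictor = prob,
                               levels = c(0, 1), direction = "<",
                               quiet = TRUE)),
    n_validation = length(val_y))
}

#' Wilson score confidence interval for a proportion
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Number of Bernoulli trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`, always inside `[0, 1]`.
#' @export
#' @examples
#' wilson_interval(0.5, 100)  # c(0.4038, 0.5962)
wilson_interval <- function(p_hat, n, conf = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Run the repeated stratified cross-validation
#'
#' For each round: balanced stratified 80/20 split, nested feature selection
#' on the training rows only ([select_important()]), second-forest training
#' and validation scoring ([train_and_eval()]). Selection and training never
#' see validation rows, avoiding the double-dipping bias. Round seeds derive
#' deterministically from `config$seed`, so the whole run is reproducible.
#'
#' @param features A `patchplex_features` tibble (typically after
#'   [filter_features()]), or any data frame with a `subject_id` column and
#'   numeric feature columns.
#' @param labels 0/1 vector aligned to the rows of `features`.
#' @param config A [cv_config()].
#' @return An object of class `cv_result`: per-round tibble `rounds` (with
#'   `selected`, `train_ids` and `validation_ids` list-columns), `summary`
#'   tibble of metric means and SDs,
#'   `wilson` interval for the mean accuracy (n = pooled validation
#'   classifications over all rounds), `selection_counts` tibble, and the
#'   `config`.
#' @export
run_cv <- function(features, labels, config = cv_config()) {
  feats <- setdiff(names(features), "subject_id")
  X <- as.data.frame(features)[feats]
  stopifnot(nrow(X) == length(labels))
  seeds <- with_seed(config$seed,
                     matrix(sample.int(2147483646, config$rounds * 3),
                            ncol = 3))
  rounds <- purrr::map_dfr(seq_len(config$rounds), function(r) {
    split <- stratify_round(labels, seeds[r, 1], config$train_fraction)
    tr <- split$train_ids
    va <- split$validation_ids
    sel <- select_important(X[tr, , drop = FALSE], labels[tr], config,
                            seed = seeds[r, 2])
    res <- train_and_eval(X[tr, , drop = FALSE], labels[tr],
                          X[va, , drop = FALSE], labels[va],
                          sel, config, seed = seeds[r, 3])
    res$round <- r
    res$selected <- list(sel)
    res$train_ids <- list(tr)
    res$validation_ids <- list(va)
    res
  })
  metrics <- c("accuracy", "specificity", "sensitivity", "auc")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(rounds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(rounds[[m]]), numeric(1)))
  n_pooled <- sum(rounds$n_validation)
  counts <- table(factor(unlist(rounds$selected), levels = feats))
  structure(list(
    rounds = rounds[c("round", "accuracy", "specificity", "sensitivity",
                      "auc", "n_validation", "selected", "train_ids",
                      "validation_ids")],
    summary = summary,
    wilson = wilson_interval(summary$mean[summary$metric == "accuracy"],
                             n_pooled),
    selection_counts = tibble::tibble(feature = feats,
                                      count = as.integer(counts[feats])),
    config = config),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  auc <- x$summary[x$summary$metric == "auc", ]
  cat("<cv_result> ", nrow(x$rounds), " rounds: accuracy ",
      sprintf("%.3f +/- %.3f", acc$mean, acc$sd), " (Wilson 95% CI [",
      sprintf("%.3f, %.3f", x$wilson["lo"], x$wilson["hi"]), "]), AUC ",
      sprintf("%.3f +/- %.3f", auc$mean, auc$sd), "\n", sep = "")
  invisible(x)
}
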