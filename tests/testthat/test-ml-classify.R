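# Stratified splitting, nested importance selection, round evaluation,
# cross-validation and the Wilson interval.

make_toy_features <- function(n_per_class = 10, p_noise = 10, effect = 0,
                              seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * p_noise), ncol = p_noise)
    colnames(X) <- sprintf("S_n%03d", seq_len(p_noise))
    X[, 1] <- X[, 1] + effect * y
    df <- tibble::as_tibble(as.data.frame(X))
    df$subject_id <- sprintf("s%02d", seq_along(y))
    list(features = df[c("subject_id", colnames(X))], labels = y)
  })
}

test_that("stratified splits are balanced, disjoint and deterministic", {
  labels <- c(rep(0, 37), rep(1, 16))
  sp <- stratify_round(labels, seed = 4)
  expect_equal(length(sp$train_ids), 26)        # 13 per class
  expect_equal(length(sp$validation_ids), 6)    # 3 per class
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
  expect_equal(sum(labels[sp$train_ids]), 13)
  expect_equal(sum(labels[sp$validation_ids]), 3)
  expect_identical(sp, stratify_round(labels, seed = 4))
  expect_false(identical(sp, stratify_round(labels, seed = 5)))

  sp2 <- stratify_round(rep(c(0, 1), each = 10), seed = 1)
  expect_equal(length(sp2$train_ids), 16)
  expect_equal(length(sp2$validation_ids), 4)

  expect_error(stratify_round(c(rep(0, 4), rep(1, 10)), seed = 1),
               "at least 5")
})

test_that("importance selection finds a planted feature and is train-only", {
  cfg <- cv_config(rounds = 1, n_trees = 200, seed = 1)
  hits <- vapply(1:20, function(s) {
    toy <- make_toy_features(n_per_class = 15, p_noise = 50, effect = 3,
                             seed = s)
    sel <- select_important(toy$features[-1], toy$labels, cfg, seed = s)
    "S_n001" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # degenerate importances: constant features fall back to the full set
  const <- tibble::tibble(a = rep(1, 20), b = rep(2, 20))
  expect_warning(sel <- select_important(const, rep(c(0, 1), 10), cfg),
                 "degenerate")
  expect_setequal(sel, c("a", "b"))
})

test_that("round evaluation counts the confusion quantities correctly", {
  cfg <- cv_config(rounds = 1, n_trees = 100, seed = 2)
  # perfectly separated classes
  toy <- make_toy_features(n_per_class = 12, p_noise = 5, effect = 10,
                           seed = 3)
  tr <- c(1:9, 13:21)
  va <- c(10:12, 22:24)
  res <- train_and_eval(toy$features[tr, -1], toy$labels[tr],
                        toy$features[va, -1], toy$labels[va],
                        selected = "S_n001", cfg)
  expect_equal(res$accuracy, 1)
  expect_equal(res$auc, 1)

  expect_error(train_and_eval(toy$features[tr, -1], toy$labels[tr],
                              toy$features[10:12, -1], toy$labels[10:12],
                              "S_n001", cfg), "single class")
})

test_that("label-permuted data classifies at chance", {
  accs <- vapply(1:20, function(s) {
    toy <- make_toy_features(n_per_class = 10, p_noise = 8, effect = 0,
                             seed = 600 + s)
    cfg <- cv_config(rounds = 1, n_trees = 100, seed = s)
    sp <- stratify_round(toy$labels, seed = s)
    sel <- select_important(toy$features[sp$train_ids, -1],
                            toy$labels[sp$train_ids], cfg, seed = s)
    train_and_eval(toy$features[sp$train_ids, -1], toy$labels[sp$train_ids],
                   toy$features[sp$validation_ids, -1],
                   toy$labels[sp$validation_ids], sel, cfg,
                   seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("run_cv is reproducible, bounded and strong on separable data", {
  toy <- make_toy_features(n_per_class = 10, p_noise = 6, effect = 4,
                           seed = 11)
  cfg <- cv_config(rounds = 10, n_trees = 100, seed = 7)
  cv1 <- run_cv(toy$features, toy$labels, cfg)
  cv2 <- run_cv(toy$features, toy$labels, cfg)
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$selection_counts, cv2$selection_counts)

  expect_true(all(cv1$selection_counts$count <= 10))
  expect_true(all(unlist(cv1$rounds[c("accuracy", "specificity",
                                      "sensitivity", "auc")]) >= 0))
  expect_true(all(unlist(cv1$rounds[c("accuracy", "specificity",
                                      "sensitivity", "auc")]) <= 1))
  acc <- cv1$summary$mean[cv1$summary$metric == "accuracy"]
  expect_gte(acc, 0.9)
  expect_gte(cv1$wilson["lo"], 0)
  expect_lte(acc, cv1$wilson["hi"] + 1e-12)
  expect_gte(acc, cv1$wilson["lo"] - 1e-12)

  gl <- glance(cv1)
  expect_equal(gl$accuracy, acc)
  td <- tidy(cv1)
  expect_equal(sum(td$count), sum(cv1$selection_counts$count))
})

test_that("selection is blind to validation rows", {
  toy <- make_toy_features(n_per_class = 10, p_noise = 6, effect = 1,
                           seed = 13)
  cfg <- cv_config(rounds = 6, n_trees = 100, seed = 3)
  cv1 <- run_cv(toy$features, toy$labels, cfg)
  # corrupt one subject's features wholesale; rounds that never trained on it
  # must select identically
  victim <- 5
  toy2 <- toy$features
  toy2[victim, -1] <- as.list(rep(1e6, ncol(toy2) - 1))
  cv2 <- run_cv(toy2, toy$labels, cfg)
  unaffected <- !vapply(cv1$rounds$train_ids, function(tr) victim %in% tr,
                        logical(1))
  expect_gt(sum(unaffected), 0)
  for (r in which(unaffected)) {
    expect_identical(cv1$rounds$selected[[r]], cv2$rounds$selected[[r]])
  }
})

test_that("the Wilson interval matches its closed form and stays in [0,1]", {
  ci <- wilson_interval(0.5, 100)
  expect_equal(unname(round(ci, 4)), c(0.4038, 0.5962))
  expect_equal(unname(wilson_interval(0, 50)["lo"]), 0)
  expect_error(wilson_interval(0.5, 0), "n must be")
  set.seed(9)
  for (i in 1:200) {
    ci <- wilson_interval(runif(1), sample(1:500, 1))
    expect_gte(ci["lo"], 0)
    expect_lte(ci["hi"], 1)
    expect_lte(ci["lo"], ci["hi"])
  }
})
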