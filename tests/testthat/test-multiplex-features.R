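# Nodal metrics, multiplex weighting, the 8N feature matrix and its filter.

test_that("hand-computed nodal metrics are reproduced", {
  # node with two links of weight 0.5: strength 1, IPR 0.5, 1/y = k = 2
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.5
  layer <- structure(list(subject_id = "a", weights = W, node_ids = 1:3),
                     class = "layer_network")
  lf <- layer_features(layer)
  expect_equal(lf$strength[1], 1.0)
  expect_equal(lf$ipr[1], 0.5)
  expect_equal(1 / lf$ipr[1], lf$degree[1])

  # illustrative unequal weights (formula in isolation): y = 0.81 + 0.01
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 0.9
  W2[1, 3] <- W2[3, 1] <- 0.1
  layer2 <- structure(list(subject_id = "a", weights = W2, node_ids = 1:3),
                      class = "layer_network")
  expect_equal(layer_features(layer2)$ipr[1], 0.82)
})

test_that("conditional means average within degree classes", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.4   # node1: deg 2 (edges to 2 and 4)
  W[1, 4] <- W[4, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.8   # node2: deg 2; node3: deg 1; node4: deg 1
  layer <- structure(list(subject_id = "a", weights = W, node_ids = 1:4),
                     class = "layer_network")
  lf <- layer_features(layer)
  expect_equal(lf$degree, c(2L, 2L, 1L, 1L))
  expect_equal(lf$strength, c(0.8, 1.2, 0.8, 0.4))
  expect_equal(lf$strength_cond, c(1.0, 1.0, 0.6, 0.6))
})

test_that("metrics match the naive double-loop oracle to 1e-12", {
  for (s in 1:25) {
    layer <- random_layer(8, seed = 300 + s)
    lf <- layer_features(layer)
    o <- oracle_layer_metrics(layer$weights)
    expect_equal(lf$degree, as.integer(o$k))
    expect_equal(lf$strength, o$s, tolerance = 1e-12)
    expect_equal(lf$ipr, o$y, tolerance = 1e-12)
    expect_equal(lf$strength_cond, o$s_cond, tolerance = 1e-12)
    expect_equal(lf$ipr_cond, o$y_cond, tolerance = 1e-12)
    # conservation: sum_k N_k * s(k) = sum_i s_i
    cls <- unique(lf$degree)
    Nk <- vapply(cls, function(k) sum(lf$degree == k), numeric(1))
    sk <- vapply(cls, function(k) mean(lf$strength[lf$degree == k]),
                 numeric(1))
    expect_equal(sum(Nk * sk), sum(lf$strength), tolerance = 1e-12)
  }
})

test_that("multiplex weighting follows the declared convention", {
  lf <- tibble::tibble(node = 1:3, degree = c(1L, 1L, 0L),
                       strength = c(0.5, 0.5, 0.0),
                       ipr = c(1, 1, 0),
                       strength_cond = c(0.5, 0.5, 0),
                       ipr_cond = c(1, 1, 0))
  out <- multiplex_node_features(lf, k_multi = c(2, 1, 1))
  expect_equal(out$multi_strength, c(0.5, 0.25, 0.0))
  expect_equal(out$multi_strength_cond, c(0.5, 0.25, 0.25))

  # complete multiplex: weighting factor 1, multiS = S, multiY = Y
  layer <- random_layer(6, seed = 9, density = 1)
  lf2 <- layer_features(layer)
  out2 <- multiplex_node_features(lf2, k_multi = rep(5, 6))
  expect_equal(out2$multi_strength, lf2$strength)
  expect_equal(out2$multi_ipr, lf2$ipr)

  # multiplex-isolated node: zero multiplex metrics
  out3 <- multiplex_node_features(lf, k_multi = c(2, 2, 0))
  expect_equal(out3$multi_strength[3], 0)
  expect_equal(out3$multi_ipr[3], 0)

  expect_error(multiplex_node_features(lf[1, ], k_multi = 1), "2 nodes")
})

test_that("feature matrix has 8 blocks of N named columns, one row/subject", {
  layers <- lapply(1:5, function(i) random_layer(8, seed = 40 + i,
                                                 subject_id = paste0("s", i)))
  mx <- assemble_multiplex(layers)
  fm <- build_feature_matrix(mx)
  expect_equal(dim(fm), c(5, 1 + 8 * 8))
  feats <- setdiff(names(fm), "subject_id")
  expect_equal(anyDuplicated(feats), 0)
  parsed <- parse_feature_names(feats)
  expect_equal(sort(unique(parsed$metric)),
               sort(c("S", "Y", "Sc", "Yc", "multiS", "multiY", "multiSc",
                      "multiYc")))
  expect_equal(unname(table(parsed$metric)["multiS"]), 8, ignore_attr = TRUE)

  # identical subjects give identical rows
  mx2 <- assemble_multiplex(list(layers[[1]], layers[[1]], layers[[2]]))
  fm2 <- build_feature_matrix(mx2)
  expect_equal(as.numeric(fm2[1, -1]), as.numeric(fm2[2, -1]))
})

test_that("IPR bound holds on random layers with uniform-weight equality", {
  for (s in 1:20) {
    layer <- random_layer(8, seed = 500 + s)
    lf <- layer_features(layer)
    con <- lf$degree >= 1
    expect_true(all(1 / lf$ipr[con] >= 1 - 1e-9))
    expect_true(all(1 / lf$ipr[con] <= lf$degree[con] + 1e-9))
  }
  # equality at k for exactly uniform weights
  W <- matrix(0.4, 5, 5); diag(W) <- 0
  layer <- structure(list(subject_id = "u", weights = W, node_ids = 1:5),
                     class = "layer_network")
  lf <- layer_features(layer)
  expect_equal(1 / lf$ipr, as.numeric(lf$degree), tolerance = 1e-9)
})

test_that("the feature filter drops constants and later correlated columns", {
  set.seed(77)
  base <- tibble::tibble(subject_id = paste0("s", 1:10),
                         S_n001 = rnorm(10), S_n002 = rnorm(10))
  base$S_n003 <- 0                              # constant zero
  base$S_n004 <- base$S_n001                    # duplicate of column 1
  base$S_n005 <- rnorm(10)
  x <- patchplex:::new_patchplex_features(
    base, dropped = tibble::tibble(feature = character(0),
                                   reason = character(0),
                                   partner = character(0)))
  f <- filter_features(x)
  d <- dropped_features(f)
  expect_setequal(d$feature, c("S_n003", "S_n004"))
  expect_equal(d$reason[d$feature == "S_n003"], "null_mean_variance")
  expect_equal(d$reason[d$feature == "S_n004"], "high_correlation")
  expect_equal(d$partner[d$feature == "S_n004"], "S_n001")
  expect_setequal(setdiff(names(f), "subject_id"),
                  c("S_n001", "S_n002", "S_n005"))

  # correlation of exactly 0.90 survives the 0.95 filter
  y <- base[c("subject_id", "S_n001")]
  eps <- residuals(lm(rnorm(10) ~ y$S_n001))
  y$S_n002 <- y$S_n001 +
    eps * sqrt(var(y$S_n001) * (1 / 0.90^2 - 1) / var(eps))
  y2 <- patchplex:::new_patchplex_features(
    y, dropped = tibble::tibble(feature = character(0),
                                reason = character(0),
                                partner = character(0)))
  f2 <- filter_features(y2)
  expect_equal(ncol(f2), 3)

  # idempotence
  ff <- filter_features(f)
  expect_equal(as.data.frame(ff), as.data.frame(f))
})
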