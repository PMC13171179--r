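test_that("the cluster forest separates separable clusters and validates input", {
  set.seed(41)
  x <- cbind(t1 = c(rnorm(20, -3), rnorm(20, 3)), t2 = rnorm(40))
  labels <- rep(1:2, each = 20)
  f <- fit_cluster_classifier(x, labels, n_estimators = 50, seed = 3)
  expect_equal(f$train_accuracy, 1)
  expect_error(fit_cluster_classifier(x, rep(1, 40)), "2 clusters")
  expect_warning(fit_cluster_classifier(x, c(rep(1, 37), 2, 2, 2), seed = 1),
                 "fewer than 5")
})

test_that("seeded forest refits are deterministic end to end", {
  sim <- small_sim(seed = 6, n = 60, groups = 3)
  x <- preprocess_traits(sim$trait_table)
  d1 <- diagnose_clusters(x, sim$planted_labels, n_estimators = 30, seed = 11)
  d2 <- diagnose_clusters(x, sim$planted_labels, n_estimators = 30, seed = 11)
  expect_identical(d1$rankings, d2$rankings)
})

test_that("permuted labels drop out-of-bag accuracy to chance", {
  set.seed(42)
  sim <- small_sim(seed = 9, n = 90, groups = 3, separation = 5)
  x <- preprocess_traits(sim$trait_table)
  accs <- replicate(10, {
    perm <- sample(sim$planted_labels)
    f <- fit_cluster_classifier(x, perm, n_estimators = 50,
                                seed = sample.int(1e6, 1))
    oob <- f$fit$predictions
    pred <- colnames(oob)[max.col(oob, ties.method = "first")]
    mean(pred == as.character(perm))
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("SHAP contributions are additive for every specimen and class", {
  sim <- small_sim(seed = 12, n = 80, groups = 3)
  x <- preprocess_traits(sim$trait_table)
  f <- fit_cluster_classifier(x, sim$planted_labels, n_estimators = 40, seed = 5)
  dec <- shap_decompose(f, x)
  pred <- stats::predict(f$fit, data.frame(unclass(x), check.names = FALSE))$predictions
  for (c_i in seq_along(dec$classes)) {
    recon <- dec$base_values[c_i] + rowSums(dec$contributions[, , c_i])
    expect_lt(max(abs(recon - pred[, dec$classes[c_i]])), 1e-6)
  }
})

test_that("a constant trait receives zero contribution everywhere", {
  set.seed(43)
  x <- cbind(sig = c(rnorm(20, -2), rnorm(20, 2)),
             flat = rep(1.5, 40), noise = rnorm(40))
  labels <- rep(1:2, each = 20)
  f <- fit_cluster_classifier(x, labels, n_estimators = 30, seed = 2)
  dec <- shap_decompose(f, x)
  expect_true(all(dec$contributions[, "flat", ] == 0))
})

test_that("TreeSHAP equals brute-force Shapley enumeration on toy trees", {
  # hand-built depth-2 tree on 2 features (0-based arrays, scalar leaf value)
  tree <- list(
    left = c(1L, 3L, -1L, -1L, -1L),
    right = c(2L, 4L, -1L, -1L, -1L),
    feature = c(0L, 1L, -1L, -1L, -1L),
    threshold = c(0.0, 1.0, 0, 0, 0),
    node_weight = c(10, 6, 4, 2, 4),
    values = matrix(c(0, 0, 5, 1, 3), ncol = 1)
  )
  for (xv in list(c(-1, 0.5), c(-1, 2), c(1, 0), c(0, 1))) {
    got <- morphograph:::tree_shap_cpp(tree$left, tree$right, tree$feature,
                                       tree$threshold, tree$node_weight,
                                       tree$values, matrix(xv, nrow = 1))
    expect_equal(matrix(got[1, , ], ncol = 1),
                 bf_tree_shapley(tree, xv, 2), tolerance = 1e-10)
    # local accuracy: base + sum(phi) = prediction
    base <- sum(tree$node_weight[tree$left < 0] *
                  tree$values[tree$left < 0, ]) / sum(tree$node_weight[tree$left < 0])
    expect_equal(base + sum(got[1, , 1]),
                 tree_value_fn(tree, xv, 1:2)[1], tolerance = 1e-10)
  }

  # trees grown by ranger on 3 features, compared leaf-for-leaf
  set.seed(44)
  x <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- factor(ifelse(x[, 1] + 0.5 * x[, 2] > 0, "a", "b"))
  f <- fit_cluster_classifier(x, as.integer(y), n_estimators = 5, seed = 9)
  for (t_id in 1:5) {
    tr <- morphograph:::ranger_tree_arrays(f, t_id)
    tree <- list(left = tr$left, right = tr$right, feature = tr$feature,
                 threshold = tr$threshold, node_weight = tr$node_weight,
                 values = tr$values)
    for (row in c(1, 17)) {
      got <- morphograph:::tree_shap_cpp(tr$left, tr$right, tr$feature,
                                         tr$threshold, tr$node_weight,
                                         tr$values, x[row, , drop = FALSE])
      expect_equal(got[1, , ], bf_tree_shapley(tree, x[row, ], 3),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("rankings surface the trait that defines a planted group", {
  set.seed(45)
  n <- 90
  x <- cbind(marker = c(rnorm(30, 6), rnorm(60, 0)),
             t2 = rnorm(n), t3 = rnorm(n), t4 = rnorm(n))
  x <- standardize_traits(x)
  labels <- rep(1:3, each = 30)
  d <- diagnose_clusters(x, labels, n_estimators = 60, seed = 7, top_n = 4)
  expect_identical(d$rankings[["1"]]$trait[1], "marker")

  # top_n = P returns the full ranking, sorted descending
  expect_equal(nrow(d$rankings[["2"]]), 4L)
  for (r in d$rankings) {
    expect_true(all(diff(r$mean_abs_shap) <= 1e-12))
    expect_true(all(r$mean_abs_shap >= 0))
  }

  d2 <- diagnose_clusters(x, labels, n_estimators = 60, seed = 7, top_n = 2)
  expect_true(all(vapply(d2$rankings, nrow, integer(1)) == 2L))
})
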