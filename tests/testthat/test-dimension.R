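test_that("edge AUC matches hand counts and handles ties", {
  # 3 edges at 3 distinct nodes is awkward to draw; build scores directly on
  # a 4-node path graph and overwrite the decoded scores pairwise
  g <- morpho_graph(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                          c(0, 1, 0, 1), c(1, 0, 1, 0)))
  # perfect ranking
  ah <- as.matrix(g$adjacency) * 0.9 + 0.05
  expect_equal(edge_auc(ah, g), 1)
  # constant scores give 1/2 under the tie convention
  expect_equal(edge_auc(matrix(0.3, 4, 4), g), 0.5)

  # 3 edges scored {.9,.8,.4} vs 3 non-edges {.7,.3,.2} -> 8/9
  g2 <- morpho_graph(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                           c(1, 0, 0, 0), c(1, 0, 0, 0)))
  ah2 <- matrix(0, 4, 4)
  ah2[1, 2] <- ah2[2, 1] <- 0.9
  ah2[1, 3] <- ah2[3, 1] <- 0.8
  ah2[1, 4] <- ah2[4, 1] <- 0.4
  ah2[2, 3] <- ah2[3, 2] <- 0.7
  ah2[2, 4] <- ah2[4, 2] <- 0.3
  ah2[3, 4] <- ah2[4, 3] <- 0.2
  expect_equal(edge_auc(ah2, g2), 8 / 9)

  expect_error(edge_auc(matrix(0.5, 2, 2), morpho_graph(rbind(c(0, 1), c(1, 0)))),
               "no edges or no non-edges")
})

test_that("edge AUC equals the brute-force pair count on random instances", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    g <- morpho_graph(random_graph(n))
    ah <- matrix(0, n, n)
    ah[upper.tri(ah)] <- sample(seq(0.05, 0.95, by = 0.05),
                                sum(upper.tri(ah)), replace = TRUE)
    ah <- ah + t(ah)
    ut <- upper.tri(ah)
    expect_equal(edge_auc(ah, g),
                 bf_auc(ah[ut], as.matrix(g$adjacency)[ut] > 0),
                 tolerance = 1e-12)
  }
})

test_that("trustworthiness is 1 for isometries and matches the rank oracle", {
  set.seed(22)
  x <- matrix(rnorm(20 * 4), 20)
  expect_equal(trustworthiness(x, x, 4), 1)

  theta <- 0.7
  rot <- diag(4)
  rot[1:2, 1:2] <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  expect_equal(trustworthiness(x, x %*% rot + 5, 4), 1)

  expect_error(trustworthiness(x, x, 10), "N/2")

  for (rep in 1:50) {
    n <- sample(8:30, 1)
    k <- sample(seq_len(floor((n - 1) / 2)), 1)
    xi <- matrix(rnorm(n * 3), n)
    zi <- matrix(rnorm(n * 2), n)
    expect_equal(trustworthiness(xi, zi, k), bf_trustworthiness(xi, zi, k),
                 tolerance = 1e-12)
  }
})

test_that("distance correlation behaves on identity, scaling and hand cases", {
  set.seed(23)
  x <- matrix(rnorm(12 * 3), 12)
  expect_equal(distance_correlation(x, x), 1)
  expect_equal(distance_correlation(x, 3.7 * x), 1)

  # 4-point instance against the explicit Pearson sum formula on 6 pairs
  x4 <- matrix(c(0, 1, 3, 7), ncol = 1)
  z4 <- matrix(c(0, 2, 3, 4), ncol = 1)
  dx <- as.vector(dist(x4)); dz <- as.vector(dist(z4))
  num <- sum((dx - mean(dx)) * (dz - mean(dz)))
  den <- sqrt(sum((dx - mean(dx))^2) * sum((dz - mean(dz))^2))
  expect_equal(distance_correlation(x4, z4), num / den, tolerance = 1e-12)

  # the formal distance correlation is non-negative and 1 on identity
  expect_equal(distance_correlation(x, x, method = "szekely"), 1)
  z <- matrix(rnorm(12 * 2), 12)
  expect_gte(distance_correlation(x, z, method = "szekely"), 0)

  expect_error(distance_correlation(matrix(1, 3, 2), matrix(1:6, 3)),
               "zero-variance")
})

test_that("dimensionality evaluation is deterministic and well-formed", {
  sim <- small_sim(seed = 7, n = 45, groups = 3, n_morph = 5, n_mer = 3)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 4)
  cfg <- gae_config(d = 2, epochs = 150, seed = 99)
  r1 <- evaluate_dims(x, g, d_range = 2, cfg)
  expect_equal(nrow(r1), 1L)
  expect_true(all(c("auc", "trustworthiness", "rho_dist", "l_bce") %in% names(r1)))
  r2 <- evaluate_dims(x, g, d_range = 2, cfg)
  expect_identical(r1, r2)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  expect_true(r1$l_bce >= 0)
})

test_that("some small dimensionality embeds planted groups faithfully", {
  sim <- small_sim(seed = 8, n = 60, groups = 3, separation = 4,
                   n_morph = 6, n_mer = 3)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 4)
  rep <- evaluate_dims(x, g, d_range = 2:4,
                       gae_config(d = 2, epochs = 400, seed = 31))
  expect_gte(max(rep$trustworthiness), 0.9)
})

test_that("dimension selection implements the plateau rule", {
  rep <- data.frame(d = 1:10,
                    auc = 0.9,
                    trustworthiness = c(0.5, 0.6, 0.7, 0.8, 0.85, 0.88,
                                        0.895, 0.93, 0.94, 0.95),
                    rho_dist = 0.1,
                    l_bce = c(2, 1.5, 1.2, 1.0, 0.9, 0.85, 0.83, 0.828,
                              0.827, 0.8265))
  expect_identical(select_dim(rep), 8L)
  # invariant to row order
  expect_identical(select_dim(rep[sample(10), ]), 8L)

  rep_low <- rep
  rep_low$trustworthiness <- rep_low$trustworthiness * 0.5
  expect_warning(d <- select_dim(rep_low), "argmax")
  expect_identical(d, 10L)

  rep_flat <- data.frame(d = 1:4, auc = 0.9, trustworthiness = 0.95,
                         rho_dist = 0, l_bce = 1)
  expect_identical(select_dim(rep_flat), 1L)
})
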