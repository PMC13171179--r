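test_that("adjacency normalisation matches hand-computed cases", {
  expect_equal(as.matrix(normalize_adjacency(matrix(0, 1, 1))),
               matrix(1), ignore_attr = TRUE)

  two <- rbind(c(0, 1), c(1, 0))
  expect_equal(as.matrix(normalize_adjacency(two)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)

  set.seed(1)
  a <- random_graph(8)
  an <- as.matrix(normalize_adjacency(a))
  expect_lt(max(abs(an - t(an))), 1e-12)
  # direct evaluation of the formula
  at <- a + diag(8)
  dm <- diag(1 / sqrt(rowSums(at)))
  expect_equal(an, dm %*% at %*% dm, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the inner-product decoder evaluates the sigmoid closed form", {
  z0 <- matrix(0, 3, 2)
  expect_equal(decode_embedding(z0), matrix(0.5, 3, 3))

  z <- rbind(c(sqrt(log(3)), 0), c(sqrt(log(3)), 0))
  expect_equal(decode_embedding(z)[1, 2], 0.75)

  set.seed(2)
  zr <- matrix(rnorm(12), 4)
  ah <- decode_embedding(zr)
  expect_identical(ah, t(ah))
  expect_true(all(ah > 0 & ah < 1))
})

test_that("weighted BCE matches its closed forms and auto weight", {
  g <- morpho_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(weighted_bce(matrix(0.5, 3, 3), g, pos_weight = 1), log(2))

  # near-perfect reconstruction has near-zero loss
  perfect <- as.matrix(g$adjacency)
  perfect[perfect == 0] <- 1e-9
  perfect[perfect == 1] <- 1 - 1e-9
  expect_lt(weighted_bce(perfect, g, pos_weight = 1), 1e-5)

  # auto positive weight = off-diagonal non-edges / edges, frozen from the
  # printed 484-node, 1184-edge graph
  set.seed(4)
  pairs <- matrix(0, 484, 484)
  up <- which(upper.tri(pairs))
  pairs[sample(up, 1184)] <- 1
  g2 <- morpho_graph(pairs + t(pairs))
  expect_equal(morphograph:::resolve_pos_weight("auto", g2),
               (484 * 483 - 2 * 1184) / (2 * 1184))
  expect_equal(round(morphograph:::resolve_pos_weight("auto", g2), 2), 97.72)
})

test_that("the fused loss kernel agrees with the reference implementation", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 7
    g <- morpho_graph(random_graph(n))
    z <- matrix(rnorm(n * 3), n)
    lg <- morphograph:::bce_loss_grad_cpp(tcrossprod(z),
                                          as.matrix(g$adjacency), 3.5)
    expect_equal(lg$loss, weighted_bce(decode_embedding(z), g, 3.5),
                 tolerance = 1e-12)
    ref <- morphograph:::bce_grad_z(z, as.matrix(g$adjacency), 3.5)
    expect_equal(2 * (lg$grad %*% z), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the analytic loss gradient matches central finite differences", {
  set.seed(6)
  n <- 6
  g <- morpho_graph(random_graph(n))
  a <- as.matrix(g$adjacency)
  z <- matrix(rnorm(n * 2, sd = 0.5), n)
  pw <- 5
  analytic <- morphograph:::bce_grad_z(z, a, pw)
  h <- 1e-5
  numeric <- z * 0
  for (i in seq_len(n)) for (j in 1:2) {
    zp <- z; zp[i, j] <- zp[i, j] + h
    zm <- z; zm[i, j] <- zm[i, j] - h
    numeric[i, j] <- (weighted_bce(decode_embedding(zp), g, pw) -
                        weighted_bce(decode_embedding(zm), g, pw)) / (2 * h)
  }
  expect_lt(max(abs(analytic - numeric)) / max(abs(numeric)), 1e-4)
})

test_that("the encoder forward pass is deterministic and linear at the head", {
  sim <- small_sim(seed = 3, n = 30, groups = 2)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 3)
  an <- normalize_adjacency(g)
  cfg <- gae_config(d = 2, hidden = c(8L, 4L), dropout = 0)
  set.seed(1)
  params <- morphograph:::gae_init_params(ncol(x), cfg)
  z1 <- gcn_forward(x, an, params, cfg)
  z2 <- gcn_forward(x, an, params, cfg)
  expect_identical(z1, z2)

  params0 <- params
  params0$W3 <- params0$W3 * 0
  expect_true(all(gcn_forward(x, an, params0, cfg) == 0))
})

test_that("a single-node forward pass reduces to the per-layer maps", {
  cfg <- gae_config(d = 2, hidden = c(4L, 3L), dropout = 0)
  set.seed(8)
  params <- morphograph:::gae_init_params(3, cfg)
  x <- matrix(rnorm(3), 1)
  an <- normalize_adjacency(matrix(0, 1, 1))   # identity propagation
  z <- gcn_forward(x, an, params, cfg)

  ln_manual <- function(v, gain, bias) {
    xh <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
    xh * gain + bias
  }
  elu_manual <- function(v) ifelse(v > 0, v, exp(v) - 1)
  h1 <- elu_manual(ln_manual(drop(x %*% params$W1), params$g1, params$b1))
  h2 <- elu_manual(ln_manual(drop(h1 %*% params$W2), params$g2, params$b2))
  expect_equal(drop(z), drop(h2 %*% params$W3), tolerance = 1e-12)
})

test_that("training follows the stepped learning-rate schedule exactly", {
  sim <- small_sim(seed = 4, n = 20, groups = 2, n_morph = 4, n_mer = 2)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 3)
  fit <- gae_train(x, g, gae_config(d = 2, epochs = 800, seed = 5))
  expect_length(fit$trace$lr, 800)
  expect_equal(fit$trace$lr[c(1, 251, 501, 751)],
               c(0.008, 0.004, 0.002, 0.001))
  expect_length(fit$trace$loss, 800)
})

test_that("training is bitwise reproducible given a seed", {
  sim <- small_sim(seed = 4, n = 20, groups = 2, n_morph = 4, n_mer = 2)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 3)
  cfg <- gae_config(d = 2, epochs = 60, seed = 123)
  f1 <- gae_train(x, g, cfg)
  f2 <- gae_train(x, g, cfg)
  expect_identical(f1$trace$loss, f2$trace$loss)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("training separates two planted cliques in the reconstruction", {
  blocks <- matrix(0, 20, 20)
  blocks[1:10, 1:10] <- 1
  blocks[11:20, 11:20] <- 1
  diag(blocks) <- 0
  g <- morpho_graph(blocks)
  x <- standardize_traits(cbind(rep(c(0, 4), each = 10) + rnorm(20, sd = 0.1),
                                rnorm(20, sd = 0.1)))
  within <- as.logical(blocks)
  between <- !within & !diag(TRUE, 20)
  for (seed in 1:5) {
    fit <- gae_train(x, g, gae_config(d = 2, epochs = 300, seed = seed))
    expect_gt(mean(fit$a_hat[within]), mean(fit$a_hat[between]))
  }
})

test_that("the training loss decreases in trend", {
  sim <- small_sim(seed = 10, n = 40, groups = 3, n_morph = 5, n_mer = 3)
  x <- preprocess_traits(sim$trait_table)
  g <- knn_graph(x, 4)
  fit <- gae_train(x, g, gae_config(d = 3, epochs = 400, seed = 2))
  expect_lt(mean(tail(fit$trace$loss, 100)), mean(head(fit$trace$loss, 100)))
})

test_that("a fit exports as a complete portable text checkpoint", {
  sim <- small_sim(seed = 16, n = 20, groups = 2, n_morph = 4, n_mer = 2)
  x <- preprocess_traits(sim$trait_table)
  fit <- gae_train(x, knn_graph(x, 3), gae_config(d = 2, epochs = 40, seed = 3))
  dir <- file.path(tempdir(), "gae_ckpt")
  write_gae_fit(fit, dir)
  files <- list.files(dir)
  expect_true(all(c("config.json", "embedding.csv", "a_hat.csv",
                    "training_trace.csv") %in% files))
  expect_setequal(paste0("weights_", names(fit$params), ".csv"),
                  grep("^weights_", files, value = TRUE))
  z <- as.matrix(read.csv(file.path(dir, "embedding.csv")))
  expect_equal(z, fit$embedding, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
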