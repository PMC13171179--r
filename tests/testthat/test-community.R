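test_that("graph reconstruction thresholds and symmetrises", {
  ah <- rbind(c(1.0, 0.9, 0.4), c(0.9, 1.0, 0.2), c(0.4, 0.2, 1.0))
  g <- reconstruct_graph(ah, tau = 0.5)
  expect_equal(n_edges(g), 1L)
  expect_equal(g$adjacency[1, 2], 0.9)

  g0 <- reconstruct_graph(ah, tau = 0)
  expect_equal(n_edges(g0), 3L)           # complete minus diagonal
  expect_true(all(Matrix::diag(g0$adjacency) == 0))

  gb <- reconstruct_graph(ah, tau = 0.3, mode = "binary")
  expect_true(all(gb$adjacency@x %in% c(0, 1)))

  expect_error(reconstruct_graph(ah, tau = 0.95), "no edges")
})

test_that("the automatic threshold finds the valley of a bimodal mixture", {
  set.seed(31)
  n <- 40
  ah <- matrix(0, n, n)
  ut <- which(upper.tri(ah))
  lo <- sample(ut, length(ut) * 0.7)
  ah[lo] <- runif(length(lo), 0.05, 0.30)
  ah[setdiff(ut, lo)] <- runif(length(setdiff(ut, lo)), 0.80, 0.98)
  ah <- ah + t(ah)
  g <- reconstruct_graph(ah, tau = "auto")
  expect_gt(attr(g, "tau"), 0.30)
  expect_lt(attr(g, "tau"), 0.80)
  expect_equal(n_edges(g), length(setdiff(ut, lo)))
})

test_that("modularity reproduces hand-derived values", {
  tri2 <- matrix(0, 6, 6)
  tri2[1:3, 1:3] <- 1; tri2[4:6, 4:6] <- 1
  diag(tri2) <- 0
  g <- morpho_graph(tri2)
  expect_equal(modularity_q(g, rep(1, 6)), 0)              # all-in-one
  expect_equal(modularity_q(g, c(1, 1, 1, 2, 2, 2)), 0.5)  # two triangles

  tri <- morpho_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(modularity_q(tri, 1:3), -1 / 3)             # all singletons
})

test_that("modularity is invariant to relabeling and weight scaling", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    a <- random_graph(n)
    w <- a * matrix(runif(n * n, 0.5, 2), n); w <- (w + t(w)) / 2
    g <- morpho_graph(w)
    labels <- sample(1:3, n, replace = TRUE)
    q <- modularity_q(g, labels)
    expect_equal(q, bf_modularity(w, labels), tolerance = 1e-12)
    expect_equal(modularity_q(g, 4 - labels), q, tolerance = 1e-12)
    expect_equal(modularity_q(morpho_graph(w * 3.7), labels), q,
                 tolerance = 1e-12)
    # independent cross-check against igraph
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(q, igraph::modularity(ig, labels,
                                       weights = igraph::E(ig)$weight),
                 tolerance = 1e-10)
  }
})

test_that("Louvain splits two cliques joined by one edge, any seed", {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1; a[6:10, 6:10] <- 1
  diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 1
  g <- morpho_graph(a)
  truth <- rep(1:2, each = 5)
  for (seed in 1:5) {
    p <- louvain_cluster(g, seed = seed)
    expect_equal(p$n_communities, 2L)
    expect_equal(nmi(p$labels, truth), 1)
    expect_equal(p$Q, modularity_q(g, p$labels), tolerance = 1e-12)
  }
})

test_that("Louvain reaches the exhaustive optimum on small graphs", {
  set.seed(33)
  hits <- 0
  n_graphs <- 50
  for (rep in seq_len(n_graphs)) {
    n <- sample(4:8, 1)
    a <- random_graph(n)
    g <- morpho_graph(a)
    p <- louvain_cluster(g, seed = rep, best_of = 5)
    best <- bf_best_modularity(a)
    expect_gte(p$Q, 0)            # never worse than all-in-one
    if (abs(p$Q - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_graphs, 0.95)
})

test_that("Louvain on a complete graph does not fabricate structure", {
  g <- morpho_graph(matrix(1, 6, 6) - diag(6))
  p <- louvain_cluster(g, seed = 1)
  expect_gte(p$Q, 0)
  expect_equal(p$Q, bf_best_modularity(matrix(1, 6, 6) - diag(6)),
               tolerance = 1e-9)
})

test_that("Louvain agrees with an independent implementation on Q", {
  set.seed(34)
  for (rep in 1:5) {
    a <- random_graph(25, 0.15)
    g <- morpho_graph(a)
    p <- louvain_cluster(g, seed = rep, best_of = 3)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    qs <- replicate(3, {
      cl <- igraph::cluster_louvain(ig)
      igraph::modularity(ig, igraph::membership(cl))
    })
    expect_gte(p$Q, max(qs) - 0.03)
  }
})

test_that("NMI matches its contingency definition and conventions", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(5, 5, 6, 6, 7)), 1)
  expect_equal(nmi(c(1, 1, 1, 1), c(1, 2, 1, 2)), 0)     # constant labeling
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)     # independent design
  expect_error(nmi(1:3, 1:4), "equal length")

  set.seed(35)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(nmi(a, b), bf_nmi(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    perm <- c(9, 7, 8)[a]                                # relabeled
    expect_equal(nmi(perm, b), nmi(a, b), tolerance = 1e-12)
  }
})

test_that("partition validation reports Q, threshold flag and contingency", {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1; a[6:10, 6:10] <- 1; diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 1
  g <- morpho_graph(a)
  p <- louvain_cluster(g, seed = 1)
  species <- rep(c("sp1", "sp2"), each = 5)
  v <- validate_partition(g, p, species)
  expect_true(v$q_threshold_passed)        # Q ~ 0.41 here
  expect_equal(v$Q, p$Q)
  expect_equal(v$nmi_vs_taxonomy, 1)
  expect_equal(unname(rowSums(v$contingency)), c(5, 5))

  v2 <- validate_partition(g, p, rep("all", 10))
  expect_equal(v2$nmi_vs_taxonomy, 0)
})
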