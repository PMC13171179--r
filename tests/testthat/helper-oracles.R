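# Independently coded brute-force oracles. These deliberately use the most
# naive formulation available (double loops, exhaustive enumeration) so they
# share no code path with the package implementations they check.

# Trustworthiness by direct rank bookkeeping (double loop over specimens).
bf_trustworthiness <- function(x, z, k) {
  n <- nrow(x)
  dx <- as.matrix(dist(x))
  dz <- as.matrix(dist(z))
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord_in <- others[order(dx[i, others], others)]
    ord_lat <- others[order(dz[i, others], others)]
    nn_lat <- ord_lat[1:k]
    nn_in <- ord_in[1:k]
    for (j in nn_lat) {
      if (!(j %in% nn_in)) {
        total <- total + (which(ord_in == j) - k)
      }
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
bf_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Mean silhouette by the textbook per-point formula.
bf_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# NMI from an explicitly built contingency table and log-sum loops.
bf_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (i in ua) for (j in ub) {
    nij <- sum(a == i & b == j)
    if (nij > 0) mi <- mi + (nij / n) * log((nij * n) / (sum(a == i) * sum(b == j)))
  }
  ent <- function(l, u) -sum(vapply(u, function(v) {
    p <- mean(l == v); if (p > 0) p * log(p) else 0
  }, numeric(1)))
  ha <- ent(a, ua); hb <- ent(b, ub)
  if (ha + hb <= 0) return(0)
  mi / ((ha + hb) / 2)
}

# Modularity by the literal double sum over ordered node pairs.
bf_modularity <- function(adj, labels) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  k <- rowSums(adj)
  two_m <- sum(adj)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) q <- q + adj[i, j] - k[i] * k[j] / two_m
  }
  q / two_m
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (v in seq_len(next_max + 1L)) rec(c(labels, v), max(next_max, v))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search over every partition (n <= 8).
bf_best_modularity <- function(adj) {
  parts <- all_partitions(nrow(as.matrix(adj)))
  max(vapply(parts, function(p) bf_modularity(adj, p), numeric(1)))
}

# Random small undirected graph with at least one edge.
random_graph <- function(n, p_edge = 0.4) {
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- rbinom(length(up), 1, p_edge)
    a <- a + t(a)
    if (sum(a) > 0) return(a)
  }
}

# Path-dependent expectation value function of a tree for a feature subset,
# and Shapley values by direct subset enumeration (tiny feature counts only).
tree_value_fn <- function(tree, x, subset) {
  rec <- function(node) {
    if (tree$left[node + 1L] < 0) return(tree$values[node + 1L, ])
    f <- tree$feature[node + 1L]
    l <- tree$left[node + 1L]; r <- tree$right[node + 1L]
    if ((f + 1L) %in% subset) {
      if (x[f + 1L] <= tree$threshold[node + 1L]) rec(l) else rec(r)
    } else {
      wl <- tree$node_weight[l + 1L]; wr <- tree$node_weight[r + 1L]
      (wl * rec(l) + wr * rec(r)) / (wl + wr)
    }
  }
  rec(0L)
}

bf_tree_shapley <- function(tree, x, n_features) {
  n_class <- ncol(tree$values)
  phi <- matrix(0, n_features, n_class)
  feats <- seq_len(n_features)
  for (f in feats) {
    rest <- setdiff(feats, f)
    for (sz in 0:length(rest)) {
      subs <- if (sz == 0) list(integer(0)) else
        utils::combn(rest, sz, simplify = FALSE)
      w <- factorial(sz) * factorial(n_features - sz - 1) / factorial(n_features)
      for (s in subs) {
        phi[f, ] <- phi[f, ] + w * (tree_value_fn(tree, x, c(s, f)) -
                                      tree_value_fn(tree, x, s))
      }
    }
  }
  phi
}
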