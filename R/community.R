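#' Threshold a reconstructed adjacency into an undirected graph
#'
#' The decoder emits edge probabilities; clustering runs on the graph those
#' probabilities imply. Entries below `tau` are removed; the diagonal is
#' zeroed; in `"weighted"` mode surviving probabilities become edge weights,
#' in `"binary"` mode they become 1.
#'
#' The default `tau = "auto"` places the cut at the valley of the
#' off-diagonal probability distribution (Otsu's between-class-variance
#' threshold). A fixed probability cut such as 0.5 is misleading here
#' because the positive-class weight of the training loss inflates the
#' decoder's probability scale: with weight \eqn{w^+} an unweighted edge
#' posterior of 1/2 maps to a decoded value near \eqn{w^+/(w^+ + 1)}, so the
#' informative boundary between the reconstruction's "background" and
#' "community" probability masses sits well above 0.5 and depends on the
#' data. Otsu's rule finds that boundary adaptively; any numeric `tau`
#' (including 0.5) can still be forced.
#'
#' @param a_hat N x N matrix of reconstructed edge probabilities.
#' @param tau `"auto"` (Otsu) or a numeric threshold in `[0, 1)`.
#' @param mode `"weighted"` or `"binary"`.
#' @return a [morpho_graph()] with the resolved threshold in attribute
#'   `"tau"`.
#' @export
reconstruct_graph <- function(a_hat, tau = "auto", mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  A <- as.matrix(a_hat)
  if (identical(tau, "auto")) {
    tau <- otsu_threshold(A[upper.tri(A)])
  }
  stopifnot(is.numeric(tau), tau >= 0, tau < 1)
  diag(A) <- 0
  A[A < tau] <- 0
  # symmetry can drift at float precision; enforce it exactly
  A <- (A + t(A)) / 2
  if (mode == "binary") A <- (A > 0) * 1
  if (sum(A) == 0) stop("no edges survive tau = ", tau, call. = FALSE)
  g <- morpho_graph(A, binary = (mode == "binary"))
  attr(g, "tau") <- tau
  g
}

# Otsu's threshold: maximises the between-class variance of the two-class
# split of a histogram. Used to find the valley between the reconstruction's
# background and community probability masses.
otsu_threshold <- function(v, n_bins = 256L) {
  br <- seq(min(v), max(v), length.out = n_bins + 1L)
  if (br[1L] == br[n_bins + 1L]) return(br[1L])
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(w)
  mu0 <- cumsum(w * mids)
  mu_t <- mu0[n_bins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  br[which.max(sigma_b) + 1L]
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' with the weighted generalisation: \eqn{k_i} is node strength and `m` the
#' total edge weight. Positive Q means denser within-community connectivity
#' than a degree-preserving random null; values above 0.3 are conventionally
#' read as non-random community structure.
#'
#' @param g a [morpho_graph()].
#' @param labels community assignment, one label per node.
#' @return modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(g, labels) {
  stopifnot(inherits(g, "morpho_graph"), length(labels) == g$n_nodes)
  A <- g$adjacency
  two_m <- sum(A)
  if (two_m <= 0) stop("graph has no edges (m = 0)", call. = FALSE)
  lab <- as.integer(factor(labels))
  sm <- Matrix::summary(A)
  within <- sum(sm$x[lab[sm$i] == lab[sm$j]])
  strength <- Matrix::rowSums(A)
  k_c <- tapply(strength, lab, sum)
  within / two_m - sum((k_c / two_m)^2)
}

# One Louvain level: greedy local moves on an edge-list graph.
# edges: data.frame(i, j, w) with i < j (no self loops); self_w: per-node
# self-loop weight (internal weight carried by aggregated super-nodes);
# m: total weight of the ORIGINAL graph (constant across levels).
louvain_local <- function(n, edges, self_w, m, order_nodes, init = NULL) {
  nbr <- vector("list", n)
  if (nrow(edges)) {
    both <- rbind(cbind(edges$i, edges$j, edges$w), cbind(edges$j, edges$i, edges$w))
    sp <- split.data.frame(both, both[, 1L])
    for (nm in names(sp)) nbr[[as.integer(nm)]] <- sp[[nm]]
  }
  strength <- self_w * 2
  for (i in seq_len(n)) if (!is.null(nbr[[i]])) strength[i] <- strength[i] + sum(nbr[[i]][, 3L])
  comm <- if (is.null(init)) seq_len(n) else as.integer(init)
  # labels live in 1..n; n + i is node i's private label, kept free so
  # "isolate into a new community" is always an available move
  sigma_tot <- numeric(2L * n)
  for (i in seq_len(n)) sigma_tot[comm[i]] <- sigma_tot[comm[i]] + strength[i]
  moved_any <- FALSE
  repeat {
    moved_pass <- FALSE
    for (i in order_nodes) {
      ni <- nbr[[i]]
      old <- comm[i]
      if (is.null(ni)) next
      cc <- comm[ni[, 2L]]
      w_to <- tapply(ni[, 3L], cc, sum)
      comms <- as.integer(names(w_to))
      sigma_tot[old] <- sigma_tot[old] - strength[i]
      if (!(old %in% comms)) { comms <- c(comms, old); w_to <- c(w_to, 0) }
      single <- n + i
      if (old != single && sigma_tot[single] == 0) {
        comms <- c(comms, single); w_to <- c(w_to, 0)
      }
      gain <- w_to - sigma_tot[comms] * strength[i] / (2 * m)
      stay <- gain[match(old, comms)]
      best_gain <- max(gain)
      best_set <- comms[gain >= best_gain - 1e-15]
      target <- if (old %in% best_set) old else min(best_set)
      if (target != old && best_gain > stay + 1e-12) {
        comm[i] <- target
        moved_pass <- TRUE
        moved_any <- TRUE
      }
      sigma_tot[comm[i]] <- sigma_tot[comm[i]] + strength[i]
    }
    if (!moved_pass) break
  }
  list(comm = comm, moved = moved_any)
}

#' Louvain community detection
#'
#' Greedy two-phase modularity maximisation: repeated single-node moves to
#' the neighbouring community with the largest positive modularity gain
#' (node order shuffled by `seed`; ties keep the current community, else the
#' lowest community id), followed by aggregation of communities into
#' super-nodes whose self-loops carry the internal weight; the two phases
#' repeat until no move improves Q by more than 1e-12.
#'
#' @param g a [morpho_graph()] with positive total weight.
#' @param seed integer seed for the node-order shuffles.
#' @param best_of rerun the whole procedure this many times with derived
#'   seeds and keep the highest-Q partition (default 1).
#' @return list of class `partition`: `labels` (consecutive integers from 1),
#'   `n_communities`, `Q`.
#' @export
louvain_cluster <- function(g, seed = 1L, best_of = 1L) {
  stopifnot(inherits(g, "morpho_graph"))
  if (sum(g$adjacency) <= 0) stop("graph has no edges (m = 0)", call. = FALSE)
  best <- NULL
  for (r in seq_len(best_of)) {
    p <- louvain_once(g, derive_seed(seed, r - 1L))
    if (is.null(best) || p$Q > best$Q) best <- p
  }
  best
}

louvain_once <- function(g, seed) {
  A0 <- g$adjacency
  m <- sum(A0) / 2
  n0 <- g$n_nodes
  sm <- Matrix::summary(Matrix::triu(A0, 1L))
  edges0 <- data.frame(i = sm$i, j = sm$j, w = sm$x)

  # one multi-level pass: local moves (optionally seeded with an initial
  # partition at the node level), then aggregate and repeat on super-graphs
  one_pass <- function(init, pass_id) {
    edges <- edges0
    self_w <- numeric(n0)
    n <- n0
    node_of <- seq_len(n0)
    level <- 0L
    repeat {
      level <- level + 1L
      ord <- with_seed(derive_seed(seed, pass_id * 1000L + level), sample.int(n))
      res <- louvain_local(n, edges, self_w, m, ord,
                           init = if (level == 1L) init else NULL)
      comm <- as.integer(factor(res$comm))
      if (!res$moved && level > 1L) break
      node_of <- comm[node_of]
      # aggregate: communities become nodes, internal weight becomes self-loops
      n_new <- max(comm)
      ci <- comm[edges$i]; cj <- comm[edges$j]
      new_self <- numeric(n_new)
      carried <- tapply(self_w, comm, sum)
      new_self[as.integer(names(carried))] <- carried
      internal <- ci == cj
      if (any(internal)) {
        add <- tapply(edges$w[internal], ci[internal], sum)
        idx <- as.integer(names(add))
        new_self[idx] <- new_self[idx] + add
      }
      ext <- !internal
      if (any(ext)) {
        lo <- pmin(ci[ext], cj[ext]); hi <- pmax(ci[ext], cj[ext])
        key <- paste(lo, hi)
        w <- tapply(edges$w[ext], key, sum)
        parts <- do.call(rbind, strsplit(names(w), " "))
        edges <- data.frame(i = as.integer(parts[, 1L]),
                            j = as.integer(parts[, 2L]),
                            w = as.numeric(w))
      } else {
        edges <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
      }
      self_w <- new_self
      if (n_new == n) break
      n <- n_new
    }
    as.integer(factor(node_of))
  }

  # iterate passes, re-seeding each from the previous flat partition, until
  # the partition's modularity stops improving
  labels <- one_pass(init = NULL, pass_id = 1L)
  q <- modularity_q(g, labels)
  for (pass in 2L:5L) {
    cand <- one_pass(init = labels, pass_id = pass)
    q_cand <- modularity_q(g, cand)
    if (q_cand > q + 1e-12) {
      labels <- cand
      q <- q_cand
    } else break
  }
  structure(list(labels = labels, n_communities = max(labels), Q = q),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", x$n_communities, "communities, Q =",
      formatC(x$Q, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Normalised mutual information between two labelings
#'
#' Mutual information of the joint label distribution, normalised by the
#' arithmetic mean of the two Shannon entropies (natural log, 0 log 0 = 0).
#' Ranges from 0 (independence) to 1 (identical up to relabeling). If either
#' labeling is constant its entropy is zero and 0 is returned by convention.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param normalization `"arithmetic"` (default) or `"geometric"` mean of
#'   the entropies.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b, normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n == 0L) stop("empty labelings", call. = FALSE)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  denom <- if (normalization == "arithmetic") (ha + hb) / 2 else sqrt(ha * hb)
  if (denom <= 0) return(0)
  min(1, max(0, mi / denom))
}

#' Validate a partition against graph structure and taxonomy
#'
#' Two checks in one report: structural robustness (is modularity above the
#' conventional 0.3 non-randomness threshold?) and taxonomic fidelity (NMI
#' between the detected communities and the current species labels), plus
#' the species-by-cluster contingency table behind both.
#'
#' @param g a [morpho_graph()].
#' @param partition a `partition` from [louvain_cluster()].
#' @param taxonomy species label per node.
#' @param q_threshold modularity threshold (default 0.3).
#' @return list of class `validation_report` with `Q`, `q_threshold_passed`,
#'   `nmi_vs_taxonomy`, `contingency`.
#' @export
validate_partition <- function(g, partition, taxonomy, q_threshold = 0.3) {
  stopifnot(length(taxonomy) == g$n_nodes)
  q <- modularity_q(g, partition$labels)
  structure(list(
    Q = q,
    q_threshold_passed = q >= q_threshold,
    nmi_vs_taxonomy = nmi(partition$labels, taxonomy),
    contingency = table(species = taxonomy, cluster = partition$labels)
  ), class = "validation_report")
}
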