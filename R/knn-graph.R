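#' Morphospace graph objects
#'
#' A `morpho_graph` is an undirected specimen graph: a symmetric sparse
#' adjacency matrix with zero diagonal and strictly positive edge weights.
#' Binary graphs come from k-NN construction; weighted graphs from the
#' autoencoder's reconstructed adjacency.
#'
#' @param adjacency symmetric (sparse or dense) non-negative matrix, zero
#'   diagonal.
#' @param binary logical; whether all weights are 0/1.
#' @param k_used neighbour count used to build the graph, or `NA`.
#' @return object of class `morpho_graph`.
#' @export
morpho_graph <- function(adjacency, binary = NULL, k_used = NA_integer_) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  if (!Matrix::isSymmetric(A, tol = 1e-9)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(Matrix::diag(A) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (any(A@x < 0)) stop("edge weights must be positive", call. = FALSE)
  A <- Matrix::drop0(A)
  if (is.null(binary)) binary <- all(A@x == 1)
  structure(list(adjacency = A, n_nodes = nrow(A), binary = binary,
                 k_used = as.integer(k_used)),
            class = "morpho_graph")
}

#' Number of undirected edges of a morpho_graph
#' @param g a `morpho_graph`.
#' @return edge count (upper-triangle non-zeros).
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "morpho_graph"))
  Matrix::nnzero(Matrix::triu(g$adjacency, 1L))
}

#' @export
print.morpho_graph <- function(x, ...) {
  cat("morpho_graph:", x$n_nodes, "nodes,", n_edges(x), "edges,",
      if (x$binary) "binary" else "weighted",
      if (!is.na(x$k_used)) paste0("(k = ", x$k_used, ")") else "", "\n")
  invisible(x)
}

#' Directed k-nearest-neighbour adjacency
#'
#' Connects each specimen to its `k` nearest neighbours by Euclidean distance
#' on the corrected feature matrix (self excluded). Distance ties at the k-th
#' neighbour are broken towards the lowest row index, so the construction is
#' deterministic.
#'
#' @param x numeric feature matrix (rows = specimens).
#' @param k neighbours per node, `1 <= k < nrow(x)`.
#' @return sparse 0/1 matrix with exactly `k` ones per row.
#' @export
knn_directed <- function(x, k) {
  x <- unclass(x)
  n <- nrow(x)
  if (k < 1L || k >= n) stop("need 1 <= k < number of specimens", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))   # stable: ties to the lowest index
    idx[i, ] <- ord[seq_len(k)]
  }
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.integer(t(idx)),
                       x = 1, dims = c(n, n))
}

#' Symmetrise a directed k-NN adjacency
#'
#' Element-wise maximum of the matrix and its transpose, yielding an
#' undirected graph in which an edge exists if either endpoint selected the
#' other as a neighbour.
#'
#' @param directed square sparse 0/1 matrix with zero diagonal.
#' @param k_used optional neighbour count to record on the graph.
#' @return a binary [morpho_graph()].
#' @export
symmetrize_adjacency <- function(directed, k_used = NA_integer_) {
  if (any(Matrix::diag(directed) != 0)) {
    stop("directed adjacency must have a zero diagonal", call. = FALSE)
  }
  A <- pmax(directed, Matrix::t(directed))
  morpho_graph(A, binary = TRUE, k_used = k_used)
}

#' Build the symmetrised k-NN morphospace graph
#'
#' @inheritParams knn_directed
#' @return a binary [morpho_graph()].
#' @export
knn_graph <- function(x, k = 4L) {
  symmetrize_adjacency(knn_directed(x, k), k_used = k)
}

#' Summarise a morphospace graph
#'
#' @param g a `morpho_graph` with at least 2 nodes.
#' @return list with `n_nodes`, `n_edges`, `mean_degree` (2E/N) and
#'   `density` (2E / (N (N - 1))).
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "morpho_graph"))
  n <- g$n_nodes
  if (n < 2L) stop("graph summary needs at least 2 nodes", call. = FALSE)
  e <- n_edges(g)
  list(n_nodes = n, n_edges = e,
       mean_degree = 2 * e / n,
       density = 2 * e / (n * (n - 1)))
}

#' Modularity-stability sweep over k
#'
#' For each neighbour count `k`, builds the symmetrised k-NN graph and runs
#' Louvain `n_replicates` times under distinct node-order seeds, recording
#' the mean and SD of modularity and of the community count. This is the
#' evidence used to choose the graph's `k` (see [select_k()]).
#'
#' @inheritParams knn_directed
#' @param k_range integer vector of k values (default 3:10).
#' @param n_replicates Louvain replicates per k (>= 2).
#' @param seed integer master seed; replicate r of value k uses a distinct
#'   derived sub-seed.
#' @return data.frame of class `k_sweep_report` with columns `k`, `mean_Q`,
#'   `sd_Q`, `mean_n_clusters`, `sd_n_clusters`, `n_replicates`.
#' @export
sweep_k <- function(x, k_range = 3:10, n_replicates = 20L, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(x)) stop("max(k_range) must be < N", call. = FALSE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2 (SD undefined)", call. = FALSE)
  rows <- lapply(seq_along(k_range), function(ki) {
    k <- k_range[ki]
    g <- knn_graph(x, k)
    qs <- numeric(n_replicates)
    ncl <- integer(n_replicates)
    for (r in seq_len(n_replicates)) {
      p <- louvain_cluster(g, seed = derive_seed(seed, ki * 10000L + r))
      qs[r] <- p$Q
      ncl[r] <- p$n_communities
    }
    data.frame(k = k, mean_Q = mean(qs), sd_Q = stats::sd(qs),
               mean_n_clusters = mean(ncl), sd_n_clusters = stats::sd(ncl),
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("k_sweep_report", "data.frame")
  out
}

#' Select k from a sweep report
#'
#' Picks the `k` that maximises mean modularity while keeping both stability
#' SDs low: candidates are the k values whose ranks of `sd_Q` and of
#' `sd_n_clusters` both fall in the best tertile; among candidates the
#' largest `mean_Q` wins; if no k qualifies the overall `mean_Q` maximum is
#' used; remaining ties go to the smallest k. Deterministic given the report.
#'
#' @param report a `k_sweep_report` from [sweep_k()].
#' @return the selected integer k.
#' @export
select_k <- function(report) {
  stopifnot(nrow(report) >= 1L)
  n <- nrow(report)
  cut <- ceiling(n / 3)
  r_sdq <- rank(report$sd_Q, ties.method = "min")
  r_sdn <- rank(report$sd_n_clusters, ties.method = "min")
  cand <- which(r_sdq <= cut & r_sdn <= cut)
  if (length(cand) == 0L) cand <- seq_len(n)
  best <- cand[report$mean_Q[cand] == max(report$mean_Q[cand])]
  as.integer(min(report$k[best]))
}

#' Export a graph as an edge list and optional GraphML
#'
#' @param g a `morpho_graph`.
#' @param path output path for the whitespace-delimited edge list
#'   (`node_i node_j weight`, 1-based row indices).
#' @param graphml_path optional GraphML output path.
#' @param specimen_ids optional ids; written as a sidecar CSV mapping row
#'   index to id next to `path`.
#' @export
write_graph_files <- function(g, path, graphml_path = NULL, specimen_ids = NULL) {
  tri <- Matrix::triu(g$adjacency, 1L)
  sm <- Matrix::summary(tri)
  utils::write.table(data.frame(i = sm$i, j = sm$j, w = sm$x), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                              weighted = if (g$binary) NULL else TRUE)
    igraph::write_graph(ig, graphml_path, format = "graphml")
  }
  if (!is.null(specimen_ids)) {
    utils::write.csv(data.frame(node = seq_along(specimen_ids),
                                specimen_id = specimen_ids),
                     sub("\\.[^.]*$", "_nodes.csv", path), row.names = FALSE)
  }
  invisible(path)
}
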