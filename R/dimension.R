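#' Edge-reconstruction AUC
#'
#' Area under the ROC curve for the decoded edge probabilities as scores and
#' observed edge/non-edge status as labels, over all unordered off-diagonal
#' specimen pairs. Computed by the rank (Mann-Whitney) formulation, so tied
#' scores contribute 1/2.
#'
#' @param a_hat reconstructed probabilities (N x N).
#' @param g observed binary [morpho_graph()].
#' @return AUC in `[0, 1]`.
#' @export
edge_auc <- function(a_hat, g) {
  A <- as.matrix(g$adjacency)
  ah <- as.matrix(a_hat)
  stopifnot(all(dim(A) == dim(ah)))
  ut <- upper.tri(A)
  labels <- A[ut] > 0
  scores <- ah[ut]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: graph has no edges or no non-edges", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trustworthiness of an embedding
#'
#' Measures how well the latent space preserves input-space k-nearest
#' neighbourhoods:
#' \deqn{T(k) = 1 - \frac{2}{N k (2N - 3k - 1)} \sum_i \sum_{j \in U_i(k)}
#'   (r(i, j) - k)}
#' where \eqn{U_i(k)} are the points in i's latent k-neighbourhood that are
#' not in its input k-neighbourhood and \eqn{r(i,j)} ranks j by input-space
#' distance from i (nearest = 1, self excluded). 1 means every latent
#' neighbour was already an input neighbour. Distance ties are resolved
#' towards the lower index, matching the k-NN graph construction.
#'
#' @param x input feature matrix.
#' @param z latent embedding (same row count).
#' @param k neighbourhood size, `1 <= k < N/2`.
#' @return T(k) in `[0, 1]`.
#' @export
trustworthiness <- function(x, z, k = 4L) {
  x <- unclass(x); z <- as.matrix(z)
  n <- nrow(x)
  stopifnot(nrow(z) == n)
  if (k < 1L || k >= n / 2) stop("trustworthiness requires 1 <= k < N/2", call. = FALSE)
  dx <- as.matrix(stats::dist(x))
  dz <- as.matrix(stats::dist(z))
  penalty <- 0
  for (i in seq_len(n)) {
    ord_x <- order(dx[i, -i], seq_len(n)[-i])
    idx_x <- seq_len(n)[-i][ord_x]          # input-space neighbours, nearest first
    rank_x <- integer(n)
    rank_x[idx_x] <- seq_len(n - 1L)
    ord_z <- order(dz[i, -i], seq_len(n)[-i])
    nn_z <- seq_len(n)[-i][ord_z][seq_len(k)]
    nn_x <- idx_x[seq_len(k)]
    u <- setdiff(nn_z, nn_x)
    if (length(u)) penalty <- penalty + sum(rank_x[u] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' Correlation of pairwise distances between two spaces
#'
#' Default is the Mantel-style Pearson correlation between the upper-triangle
#' vectors of the two Euclidean distance matrices, which can be negative.
#' `method = "szekely"` instead computes the formal (Szekely) distance
#' correlation, which is non-negative, for users who want that statistic.
#'
#' @param x first matrix (e.g. the corrected trait matrix).
#' @param z second matrix with the same rows (e.g. the latent embedding).
#' @param method `"pearson"` (default) or `"szekely"`.
#' @return correlation in `[-1, 1]` (`[0, 1]` for `"szekely"`).
#' @export
distance_correlation <- function(x, z, method = c("pearson", "szekely")) {
  method <- match.arg(method)
  x <- unclass(x); z <- as.matrix(z)
  n <- nrow(x)
  stopifnot(nrow(z) == n, n >= 3)
  if (method == "pearson") {
    dx <- as.vector(stats::dist(x))
    dz <- as.vector(stats::dist(z))
    if (stats::sd(dx) == 0 || stats::sd(dz) == 0) {
      stop("distance correlation undefined: zero-variance distances", call. = FALSE)
    }
    stats::cor(dx, dz)
  } else {
    dc <- function(d) {
      m <- as.matrix(d)
      sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
    }
    ax <- dc(stats::dist(x)); az <- dc(stats::dist(z))
    dcov2 <- mean(ax * az)
    vx <- mean(ax * ax); vz <- mean(az * az)
    if (vx <= 0 || vz <= 0) stop("distance correlation undefined", call. = FALSE)
    sqrt(dcov2 / sqrt(vx * vz))
  }
}

#' Evaluate candidate latent dimensionalities
#'
#' Trains one autoencoder per dimensionality (each with a derived sub-seed)
#' and records four structural metrics: edge-reconstruction AUC (global
#' fidelity), trustworthiness (local neighbourhood retention), Pearson
#' correlation of pairwise distances (geometric fidelity; may be negative)
#' and the final reconstruction loss.
#'
#' @param x corrected feature matrix.
#' @param g binary [morpho_graph()].
#' @param d_range integer vector of dimensionalities to evaluate.
#' @param config a [gae_config()] (its `d` is overridden per evaluation, its
#'   `seed` is the master seed).
#' @param k neighbourhood size for trustworthiness (default: the graph's k,
#'   else 4).
#' @return data.frame of class `dimensionality_report` with columns
#'   `d`, `auc`, `trustworthiness`, `rho_dist`, `l_bce`.
#' @export
evaluate_dims <- function(x, g, d_range, config, k = NULL) {
  if (is.null(k)) k <- if (!is.na(g$k_used)) g$k_used else 4L
  d_range <- sort(unique(as.integer(d_range)))
  stopifnot(all(d_range >= 1), all(d_range <= ncol(x)))
  rows <- lapply(d_range, function(d) {
    cfg <- config
    cfg$d <- as.integer(d)
    cfg$seed <- derive_seed(config$seed, d)
    fit <- gae_train(x, g, cfg)
    data.frame(d = d,
               auc = edge_auc(fit$a_hat, g),
               trustworthiness = trustworthiness(x, fit$embedding, k),
               rho_dist = distance_correlation(x, fit$embedding),
               l_bce = fit$trace$final_loss)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dimensionality_report", "data.frame")
  out
}

#' Select the latent dimensionality
#'
#' Returns the smallest d that reaches the high-fidelity trustworthiness
#' threshold while sitting on the loss stability plateau (relative
#' improvement of the final loss from the previous d below `loss_tol`). If
#' no d qualifies, the trustworthiness argmax is returned with a warning.
#' Deterministic and invariant to row order.
#'
#' @param report a `dimensionality_report` with at least 2 rows.
#' @param t_threshold trustworthiness threshold (default 0.9).
#' @param loss_tol relative loss-improvement tolerance (default 0.01).
#' @return the selected integer d.
#' @export
select_dim <- function(report, t_threshold = 0.9, loss_tol = 0.01) {
  stopifnot(nrow(report) >= 2L)
  rep_ <- report[order(report$d), ]
  # the smallest evaluated d has no predecessor: its plateau condition is
  # vacuous, so parsimony wins if it already clears the fidelity threshold
  rel_impr <- c(0, -diff(rep_$l_bce) / pmax(abs(rep_$l_bce[-nrow(rep_)]), 1e-12))
  ok <- rep_$trustworthiness >= t_threshold & rel_impr < loss_tol
  if (any(ok)) return(as.integer(rep_$d[which(ok)[1L]]))
  warning("no dimensionality satisfies both criteria; returning argmax T(k)",
          call. = FALSE)
  best <- which(rep_$trustworthiness == max(rep_$trustworthiness))
  as.integer(rep_$d[best[1L]])
}
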