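#' PCA scores retaining a target variance fraction
#'
#' Singular-value decomposition of the (already standardised) centred matrix;
#' keeps the smallest number of components whose cumulative explained
#' variance reaches `var_target`.
#'
#' @param x corrected feature matrix.
#' @param var_target cumulative variance fraction in `(0, 1]` (default 0.95).
#' @return list with `scores` (N x m), `n_components`, `explained` (all
#'   variance ratios), `rotation`, `center`.
#' @export
pca_scores <- function(x, var_target = 0.95) {
  if (var_target <= 0 || var_target > 1) {
    stop("var_target must be in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(unclass(x), center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(ratios) >= var_target - 1e-12)[1L]
  list(scores = pc$x[, seq_len(m), drop = FALSE], n_components = m,
       explained = ratios, rotation = pc$rotation, center = pc$center)
}

#' Mean silhouette width of a clustering
#'
#' Per point, `(b - a) / max(a, b)` with `a` the mean distance to the point's
#' own cluster and `b` the smallest mean distance to another cluster;
#' singletons score 0 by convention. Euclidean distances.
#'
#' @param scores coordinate matrix.
#' @param labels cluster assignment (at least 2 non-empty clusters).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(scores, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

# Seeded k-means++ starting centres.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' k-means scan with silhouette model selection
#'
#' For each candidate cluster count, runs k-means from `n_init` seeded
#' k-means++ initialisations and keeps the lowest-inertia solution; the
#' returned `best_k` maximises the mean silhouette (ties to the smaller k).
#'
#' @param scores coordinate matrix (e.g. retained PCA scores).
#' @param k_range candidate cluster counts (default 2:15).
#' @param n_init random initialisations per k (default 10).
#' @param seed integer seed.
#' @return list with `best_k`, `labels` (for `best_k`), `silhouette_by_k`
#'   (named numeric), `labels_by_k`.
#' @export
kmeans_scan <- function(scores, k_range = 2:15, n_init = 10L, seed = 1L) {
  scores <- as.matrix(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(scores)) stop("max k must be < N", call. = FALSE)
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  labs <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- with_seed(derive_seed(seed, k * 1000L + init), {
        centers <- kmeanspp_centers(scores, k)
        suppressWarnings(stats::kmeans(scores, centers = centers,
                                       iter.max = 100L))
      })
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    labs[[ki]] <- best$cluster
    sil[ki] <- silhouette_score(scores, best$cluster)
  }
  best_i <- which(sil == max(sil))[1L]
  list(best_k = k_range[best_i], labels = labs[[best_i]],
       silhouette_by_k = sil,
       labels_by_k = stats::setNames(labs, k_range))
}

#' Linear baseline: PCA + k-means scored on a k-NN graph
#'
#' The comparative baseline for the autoencoder pipeline: PCA retaining 95%
#' of the variance, k-means over k = 2..15 with silhouette selection, then
#' modularity of the chosen k-means labels on the symmetrised k-NN graph of
#' the PCA coordinates, plus NMI against the taxonomy.
#'
#' @param x corrected feature matrix.
#' @param taxonomy species label per specimen.
#' @param var_target PCA variance target (default 0.95).
#' @param k_range k-means candidate range (default 2:15).
#' @param n_init k-means initialisations per k.
#' @param knn_k neighbour count of the scoring graph (default 4).
#' @param seed integer seed.
#' @return list of class `baseline_report`: `n_components_95`, `best_k`,
#'   `silhouette_by_k`, `Q_baseline`, `nmi_vs_taxonomy`, `labels`.
#' @export
baseline_report <- function(x, taxonomy, var_target = 0.95, k_range = 2:15,
                            n_init = 10L, knn_k = 4L, seed = 1L) {
  stopifnot(length(taxonomy) == nrow(x))
  pca <- pca_scores(x, var_target)
  scan <- kmeans_scan(pca$scores, k_range, n_init, seed)
  g <- knn_graph(pca$scores, knn_k)
  structure(list(
    n_components_95 = pca$n_components,
    best_k = scan$best_k,
    silhouette_by_k = scan$silhouette_by_k,
    Q_baseline = modularity_q(g, scan$labels),
    nmi_vs_taxonomy = nmi(scan$labels, taxonomy),
    labels = scan$labels
  ), class = "baseline_report")
}
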