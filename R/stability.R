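#' Sample trait subsets for the stability analysis
#'
#' If the number of possible subsets of size `size` does not exceed
#' `max_subsets`, all of them are enumerated (sorted); otherwise
#' `max_subsets` distinct subsets are drawn uniformly without replacement.
#' Deterministic given the seed.
#'
#' @param n_traits total number of traits P.
#' @param size subset size s, `1 <= s <= P`.
#' @param max_subsets cap on the number of subsets (default 1000).
#' @param seed integer seed.
#' @return list of integer index vectors (each sorted ascending).
#' @export
sample_subsets <- function(n_traits, size, max_subsets = 1000L, seed = 1L) {
  if (size > n_traits || size < 1L) stop("need 1 <= size <= n_traits", call. = FALSE)
  total <- choose(n_traits, size)
  if (total <= max_subsets) {
    cmb <- utils::combn(n_traits, size)
    return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", max_subsets)
    got <- 0L
    while (got < max_subsets) {
      s <- sort(sample.int(n_traits, size))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  })
}

#' Stratified variable-subset stability analysis
#'
#' Asks whether the number of detected morphotypes is a property of the data
#' rather than of the particular trait set: for each subset size, random
#' trait subsets are drawn, preprocessing is re-run on the subset, the
#' k-NN graph is rebuilt and partitioned with Louvain (mode `"graph"`), or
#' additionally the autoencoder is retrained and its reconstructed graph
#' partitioned (mode `"full_gae"`); in parallel the PCA/k-means baseline
#' re-selects its silhouette-optimal k. Distributions of community counts,
#' modularity and k-means k are aggregated per size.
#'
#' @param table a [trait_table()].
#' @param sizes subset sizes to evaluate (each in `[3, P]`).
#' @param mode `"graph"` (default, no GAE retraining) or `"full_gae"`.
#' @param max_subsets subsets per size (default 1000 for `"graph"`, 50 for
#'   `"full_gae"`).
#' @param knn_k neighbour count of the graph (default 4).
#' @param gae_cfg a [gae_config()] used in `"full_gae"` mode.
#' @param tau reconstruction threshold in `"full_gae"` mode.
#' @param kmeans_range candidate k for the baseline arm (default 2:15).
#' @param q_threshold modularity threshold for the pass proportion.
#' @param seed integer seed.
#' @return data.frame of class `stability_report`: one row per size with
#'   `size`, `n_subsets`, `n_skipped`, `mode_count`, `mean_count`,
#'   `sd_count`, `mode_kmeans_k`, `mean_kmeans_k`, `mean_Q`, `sd_Q`,
#'   `prop_Q_ge_threshold`.
#' @export
stability_run <- function(table, sizes, mode = c("graph", "full_gae"),
                          max_subsets = NULL, knn_k = 4L, gae_cfg = NULL,
                          tau = "auto", kmeans_range = 2:15, q_threshold = 0.3,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(max_subsets)) max_subsets <- if (mode == "graph") 1000L else 50L
  corrected_full <- allometric_correct(table)
  p <- ncol(corrected_full)
  stopifnot(all(sizes >= 3L), all(sizes <= p))

  stat_mode <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1L])
  rows <- lapply(seq_along(sizes), function(si) {
    s <- sizes[si]
    subsets <- sample_subsets(p, s, max_subsets, derive_seed(seed, si))
    counts <- qs <- kms <- numeric(0)
    skipped <- 0L
    for (bi in seq_along(subsets)) {
      sub <- subsets[[bi]]
      res <- tryCatch({
        x <- standardize_traits(corrected_full[, sub, drop = FALSE],
                                drop_constant = TRUE)
        if (ncol(x) < 2L) stop("degenerate subset")
        g <- knn_graph(x, knn_k)
        sub_seed <- derive_seed(seed, si * 100000L + bi)
        part <- if (mode == "graph") {
          louvain_cluster(g, seed = sub_seed)
        } else {
          cfg <- gae_cfg
          cfg$seed <- sub_seed
          fit <- gae_train(x, g, cfg)
          louvain_cluster(reconstruct_graph(fit$a_hat, tau), seed = sub_seed)
        }
        scan <- kmeans_scan(pca_scores(x)$scores, kmeans_range,
                            n_init = 10L, seed = sub_seed)
        list(n = part$n_communities, q = part$Q, km = scan$best_k)
      }, error = function(e) NULL)
      if (is.null(res)) { skipped <- skipped + 1L; next }
      counts <- c(counts, res$n); qs <- c(qs, res$q); kms <- c(kms, res$km)
    }
    data.frame(size = s, n_subsets = length(counts), n_skipped = skipped,
               mode_count = stat_mode(counts), mean_count = mean(counts),
               sd_count = stats::sd(counts),
               mode_kmeans_k = stat_mode(kms), mean_kmeans_k = mean(kms),
               mean_Q = mean(qs), sd_Q = stats::sd(qs),
               prop_Q_ge_threshold = mean(qs >= q_threshold))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_report", "data.frame")
  out
}

#' Assess a stability report
#'
#' Three criteria, each a boolean: (i) convergence - the modal community
#' count at the largest subset size equals the full-data solution;
#' (ii) decreasing spread - the SD of the community count is non-increasing
#' in trend across sizes (Spearman correlation <= 0, or a single size);
#' (iii) consistently non-random - the proportion of subsets with
#' Q >= `q_threshold` is at least `prop_threshold` at every size. The
#' verdict is their conjunction.
#'
#' @param report a `stability_report`.
#' @param full_solution_count community count of the full-data run.
#' @param q_threshold modularity threshold used in the report.
#' @param prop_threshold required pass proportion (default 0.9).
#' @return list of class `stability_verdict` with the three booleans and
#'   `stable` (their AND).
#' @export
assess_stability <- function(report, full_solution_count, q_threshold = 0.3,
                             prop_threshold = 0.9) {
  stopifnot(nrow(report) >= 1L)
  rep_ <- report[order(report$size), ]
  converged <- rep_$mode_count[nrow(rep_)] == full_solution_count
  sd_trend <- if (nrow(rep_) < 2L) TRUE else {
    suppressWarnings(stats::cor(rep_$size, rep_$sd_count, method = "spearman")) <= 0 ||
      all(rep_$sd_count == rep_$sd_count[1L])
  }
  if (is.na(sd_trend)) sd_trend <- TRUE  # constant SDs: no increasing trend
  prop_ok <- all(rep_$prop_Q_ge_threshold >= prop_threshold)
  structure(list(converged = converged, sd_non_increasing = sd_trend,
                 proportion_high = prop_ok,
                 stable = converged && sd_trend && prop_ok),
            class = "stability_verdict")
}
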