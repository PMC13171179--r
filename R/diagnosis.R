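#' Fit the cluster-diagnosis random forest
#'
#' Trains a probability random forest (default 100 trees) that predicts the
#' detected cluster of each specimen from the standardised traits. The
#' forest is not the clustering: it is the interpretable surrogate whose
#' SHAP decomposition diagnoses which traits define each morphotype.
#'
#' @param x corrected feature matrix.
#' @param labels cluster assignment (a `partition` or a vector); at least 2
#'   clusters, each with at least 2 members (a warning is issued below 5).
#' @param n_estimators number of trees (default 100).
#' @param seed integer seed (forest growth is deterministic given it).
#' @return list of class `cluster_forest`: the ranger `fit` (with in-bag
#'   counts), `trait_names`, `classes`, `train_accuracy`, `n_estimators`,
#'   `seed`.
#' @export
fit_cluster_classifier <- function(x, labels, n_estimators = 100L, seed = 1L) {
  if (inherits(labels, "partition")) labels <- labels$labels
  stopifnot(length(labels) == nrow(x))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 clusters to fit a classifier", call. = FALSE)
  if (any(tab < 2L)) stop("every cluster needs at least 2 members", call. = FALSE)
  if (any(tab < 5L)) {
    warning("cluster(s) with fewer than 5 members: ",
            paste(names(tab)[tab < 5L], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.cluster = factor(labels), unclass(x), check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".cluster", data = df,
    num.trees = n_estimators, probability = TRUE,
    keep.inbag = TRUE, seed = as.integer(seed) %% 2147483647L
  )
  prob <- stats::predict(fit, df)$predictions
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  structure(list(fit = fit, trait_names = colnames(x),
                 classes = levels(df$.cluster),
                 train_x = unclass(x),
                 train_accuracy = mean(pred == as.character(labels)),
                 n_estimators = as.integer(n_estimators), seed = seed),
            class = "cluster_forest")
}

# Extract one ranger tree as flat arrays plus training-coverage node weights.
ranger_tree_arrays <- function(forest, tree_id) {
  ti <- ranger::treeInfo(forest$fit, tree_id)
  n_nodes <- nrow(ti)
  left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
  right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
  feat <- ifelse(is.na(ti$splitvarID), -1L, as.integer(ti$splitvarID))
  thr <- ifelse(is.na(ti$splitval), 0, ti$splitval)
  pred_cols <- grep("^pred\\.", names(ti))
  vals <- as.matrix(ti[, pred_cols, drop = FALSE])
  vals[is.na(vals)] <- 0
  colnames(vals) <- sub("^pred\\.", "", names(ti)[pred_cols])

  x <- forest$train_x
  w <- forest$fit$inbag.counts[[tree_id]]
  node_w <- numeric(n_nodes)
  node_w[1L] <- sum(w)
  cur <- rep(1L, nrow(x))          # 1-based node ids
  active <- which(w > 0)
  while (length(active)) {
    cn <- cur[active]
    internal <- left[cn] >= 0L
    active <- active[internal]
    if (!length(active)) break
    cn <- cn[internal]
    go_left <- x[cbind(active, feat[cn] + 1L)] <= thr[cn]
    nxt <- ifelse(go_left, left[cn], right[cn]) + 1L
    cur[active] <- nxt
    add <- rowsum(w[active], nxt)
    ids <- as.integer(rownames(add))
    node_w[ids] <- node_w[ids] + add[, 1L]
  }
  list(left = left, right = right, feature = feat, threshold = thr,
       node_weight = node_w, values = vals)
}

#' SHAP decomposition of the cluster forest
#'
#' Path-dependent TreeSHAP over every tree: for each specimen and cluster
#' class, the predicted class probability decomposes exactly into a base
#' value (the coverage-weighted expectation) plus one additive contribution
#' per trait.
#'
#' @param forest a `cluster_forest` from [fit_cluster_classifier()].
#' @param x feature matrix with the same trait columns the forest was
#'   trained on.
#' @return list of class `shap_decomposition`: `contributions` (array
#'   specimens x traits x classes), `base_values` (per class), `classes`,
#'   `trait_names`.
#' @export
shap_decompose <- function(forest, x) {
  stopifnot(inherits(forest, "cluster_forest"))
  x <- unclass(x)
  if (!identical(colnames(x), forest$trait_names)) {
    stop("trait set does not match the fitted forest", call. = FALSE)
  }
  n_trees <- forest$n_estimators
  classes <- forest$classes
  phi <- array(0, dim = c(nrow(x), ncol(x), length(classes)),
               dimnames = list(rownames(x), colnames(x), classes))
  base <- stats::setNames(numeric(length(classes)), classes)
  for (t in seq_len(n_trees)) {
    tr <- ranger_tree_arrays(forest, t)
    vals <- tr$values[, classes, drop = FALSE]
    phi <- phi + tree_shap_cpp(tr$left, tr$right, tr$feature, tr$threshold,
                               tr$node_weight, vals, x)
    leaf <- tr$left < 0L
    base <- base + colSums(vals[leaf, , drop = FALSE] *
                             tr$node_weight[leaf]) / sum(tr$node_weight[leaf])
  }
  structure(list(contributions = phi / n_trees, base_values = base / n_trees,
                 classes = classes, trait_names = colnames(x)),
            class = "shap_decomposition")
}

#' Per-cluster trait importance ranking
#'
#' For each cluster class, trait importance is the mean absolute SHAP
#' contribution of the trait to that class, averaged across all specimens
#' (set `members_only = TRUE` to average over the cluster's members only).
#' Only the within-cluster rank order is meaningful: absolute magnitudes are
#' partitioned across classes by the multiclass setup and are not compared
#' between clusters.
#'
#' @param decomposition a `shap_decomposition`.
#' @param labels cluster assignment used when `members_only = TRUE`
#'   (a `partition` or vector); otherwise optional.
#' @param top_n traits retained per cluster (default 10).
#' @param members_only average only over the cluster's own specimens.
#' @return list of class `shap_diagnosis`: per cluster a data.frame
#'   `(rank, trait, mean_abs_shap)` sorted descending (ties by trait name).
#' @export
cluster_trait_ranking <- function(decomposition, labels = NULL, top_n = 10L,
                                  members_only = FALSE) {
  stopifnot(inherits(decomposition, "shap_decomposition"))
  if (inherits(labels, "partition")) labels <- labels$labels
  if (members_only && is.null(labels)) {
    stop("members_only = TRUE requires cluster labels", call. = FALSE)
  }
  phi <- decomposition$contributions
  out <- lapply(decomposition$classes, function(cl) {
    rows <- if (members_only) which(as.character(labels) == cl) else seq_len(dim(phi)[1L])
    m <- abs(phi[rows, , cl, drop = FALSE])
    dim(m) <- dim(m)[1:2]
    imp <- stats::setNames(colMeans(m), decomposition$trait_names)
    ord <- order(-imp, names(imp))
    keep <- ord[seq_len(min(top_n, length(imp)))]
    data.frame(rank = seq_along(keep), trait = names(imp)[keep],
               mean_abs_shap = as.numeric(imp[keep]), row.names = NULL)
  })
  names(out) <- decomposition$classes
  structure(list(rankings = out, n_estimators = NA_integer_,
                 top_n = as.integer(top_n), members_only = members_only),
            class = "shap_diagnosis")
}

#' One-call morphological diagnosis of detected clusters
#'
#' Fits the cluster forest, runs the SHAP decomposition and returns the
#' per-cluster trait rankings.
#'
#' @inheritParams fit_cluster_classifier
#' @inheritParams cluster_trait_ranking
#' @return a `shap_diagnosis` (with `n_estimators` and the forest's training
#'   accuracy attached).
#' @export
diagnose_clusters <- function(x, labels, n_estimators = 100L, top_n = 10L,
                              members_only = FALSE, seed = 1L) {
  forest <- fit_cluster_classifier(x, labels, n_estimators, seed)
  dec <- shap_decompose(forest, x)
  diag <- cluster_trait_ranking(dec, labels, top_n, members_only)
  diag$n_estimators <- forest$n_estimators
  diag$train_accuracy <- forest$train_accuracy
  diag
}

#' Write a SHAP diagnosis as a long-format CSV
#'
#' @param diagnosis a `shap_diagnosis`.
#' @param path output CSV path (`cluster, rank, trait, mean_abs_shap`).
#' @export
write_diagnosis <- function(diagnosis, path) {
  long <- do.call(rbind, lapply(names(diagnosis$rankings), function(cl) {
    cbind(cluster = cl, diagnosis$rankings[[cl]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
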