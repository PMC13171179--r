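#' Run the full morphotype-detection pipeline
#'
#' Preprocess -> (optional k sweep) -> k-NN graph -> (optional latent
#' dimension scan) -> autoencoder training -> graph reconstruction ->
#' Louvain partition -> validation -> SHAP diagnosis -> PCA baseline ->
#' optional stability analysis. One master seed derives a fixed sub-seed per
#' stage, so stages are individually reproducible. When `output_dir` is
#' given, stage artifacts (CSV/JSON) and a run manifest are written.
#'
#' @param table a [trait_table()] (or a `simulated_dataset`, whose planted
#'   labels are then carried into the manifest).
#' @param k neighbour count; `NULL` runs [sweep_k()] + [select_k()].
#' @param d latent dimensionality; `NULL` runs [evaluate_dims()] +
#'   [select_dim()] over `d_range`.
#' @param d_range dimensionalities scanned when `d` is `NULL`.
#' @param gae options passed to [gae_config()] (list; `d`/`seed` are set by
#'   the pipeline).
#' @param tau,mode reconstruction threshold and mode (see
#'   [reconstruct_graph()]).
#' @param top_n traits per cluster in the diagnosis.
#' @param run_stability run [stability_run()] (graph mode) at
#'   `stability_sizes`.
#' @param stability_sizes subset sizes for the stability stage.
#' @param stability_max_subsets subsets per size for the stability stage.
#' @param output_dir directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @param seed master seed.
#' @return list of class `pipeline_result` with every stage's object
#'   (`corrected`, `k`, `graph`, `d`, `gae_fit`, `recon_graph`, `partition`,
#'   `validation`, `diagnosis`, `baseline`, optional `ksweep`, `dim_report`,
#'   `stability`) and a `manifest` of parameters and output paths.
#' @export
run_pipeline <- function(table, k = 4L, d = 8L, d_range = NULL,
                         gae = list(), tau = "auto",
                         mode = c("weighted", "binary"), top_n = 10L,
                         run_stability = FALSE,
                         stability_sizes = c(5L, 10L, 15L),
                         stability_max_subsets = 100L,
                         output_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  planted <- NULL
  if (inherits(table, "simulated_dataset")) {
    planted <- table$planted_labels
    table <- table$trait_table
  }
  stopifnot(inherits(table, "trait_table"))
  out <- list()
  paths <- list()
  emit <- function(name, writer) {
    if (!is.null(output_dir)) {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      path <- file.path(output_dir, name)
      writer(path)
      paths[[name]] <<- path
    }
  }

  x <- preprocess_traits(table)
  out$corrected <- x
  emit("corrected_matrix.csv", function(p) write_corrected_matrix(x, p))

  if (is.null(k)) {
    out$ksweep <- sweep_k(x, seed = derive_seed(seed, 1L))
    k <- select_k(out$ksweep)
    emit("k_sweep.csv", function(p) utils::write.csv(out$ksweep, p, row.names = FALSE))
  }
  out$k <- k
  g <- knn_graph(x, k)
  out$graph <- g
  emit("knn_graph_edges.txt", function(p)
    write_graph_files(g, p, specimen_ids = table$specimen_id))

  base_cfg <- do.call(gae_config, c(list(d = if (is.null(d)) 2L else d), gae))
  if (is.null(d)) {
    if (is.null(d_range)) d_range <- seq_len(ncol(x))
    cfg_scan <- base_cfg
    cfg_scan$seed <- derive_seed(seed, 2L)
    out$dim_report <- evaluate_dims(x, g, d_range, cfg_scan)
    d <- select_dim(out$dim_report)
    emit("dimension_report.csv", function(p)
      utils::write.csv(out$dim_report, p, row.names = FALSE))
  }
  out$d <- d
  cfg <- base_cfg
  cfg$d <- as.integer(d)
  cfg$seed <- derive_seed(seed, 3L)
  out$gae_fit <- gae_train(x, g, cfg)

  out$recon_graph <- reconstruct_graph(out$gae_fit$a_hat, tau, mode)
  out$partition <- louvain_cluster(out$recon_graph, seed = derive_seed(seed, 4L))
  emit("clusters.csv", function(p)
    utils::write.csv(data.frame(specimen_id = table$specimen_id,
                                cluster = out$partition$labels),
                     p, row.names = FALSE))

  taxonomy <- if (!is.null(table$species)) table$species else rep("unknown", g$n_nodes)
  out$validation <- validate_partition(out$recon_graph, out$partition, taxonomy)
  emit("validation.json", function(p)
    jsonlite::write_json(list(Q = out$validation$Q,
                              q_threshold_passed = out$validation$q_threshold_passed,
                              nmi_vs_taxonomy = out$validation$nmi_vs_taxonomy),
                         p, auto_unbox = TRUE, digits = NA))
  emit("contingency.csv", function(p)
    utils::write.csv(as.data.frame.matrix(out$validation$contingency), p))

  out$diagnosis <- diagnose_clusters(x, out$partition, top_n = top_n,
                                     seed = derive_seed(seed, 5L))
  emit("diagnosis.csv", function(p) write_diagnosis(out$diagnosis, p))

  out$baseline <- baseline_report(x, taxonomy, seed = derive_seed(seed, 6L))
  emit("baseline.json", function(p)
    jsonlite::write_json(list(n_components_95 = out$baseline$n_components_95,
                              best_k = out$baseline$best_k,
                              Q_baseline = out$baseline$Q_baseline,
                              nmi_vs_taxonomy = out$baseline$nmi_vs_taxonomy),
                         p, auto_unbox = TRUE, digits = NA))

  if (run_stability) {
    out$stability <- stability_run(table, stability_sizes,
                                   max_subsets = stability_max_subsets,
                                   knn_k = k, seed = derive_seed(seed, 7L))
    emit("stability.csv", function(p)
      utils::write.csv(out$stability, p, row.names = FALSE))
  }

  if (!is.null(output_dir)) {
    paths[["manifest.json"]] <- file.path(output_dir, "manifest.json")
  }
  out$manifest <- list(
    parameters = list(k = k, d = d, tau = tau, mode = mode, top_n = top_n,
                      seed = seed, gae = cfg[setdiff(names(cfg), "seed")],
                      run_stability = run_stability),
    n_specimens = g$n_nodes, n_traits = ncol(x),
    planted_labels_present = !is.null(planted),
    outputs = paths
  )
  if (!is.null(planted)) out$planted_labels <- planted
  emit("manifest.json", function(p)
    jsonlite::write_json(out$manifest, p, auto_unbox = TRUE, digits = NA))
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("morphograph pipeline: N =", x$graph$n_nodes,
      "| k =", x$k, "| d =", x$d,
      "|", x$partition$n_communities, "morphotypes, Q =",
      formatC(x$partition$Q, digits = 4, format = "f"),
      "| NMI vs taxonomy =",
      formatC(x$validation$nmi_vs_taxonomy, digits = 4, format = "f"), "\n")
  invisible(x)
}
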