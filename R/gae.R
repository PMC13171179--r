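#' Configuration for the graph autoencoder
#'
#' Defaults reproduce the study conditions: a three-layer graph-convolutional
#' encoder (128, 64, d units), ELU activations with layer normalisation and
#' 15% dropout between layers, 1000 epochs of full-batch Adam on a weighted
#' binary cross-entropy, and a step-decayed learning rate starting at 0.008
#' and halving every 250 epochs.
#'
#' @param d latent dimensionality (1 <= d <= number of traits).
#' @param hidden widths of the two hidden GCN layers.
#' @param dropout dropout fraction in `[0, 1)` applied after each hidden layer.
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param lr_decay_factor multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param pos_weight weight on the positive (edge) class of the loss;
#'   `"auto"` uses the off-diagonal non-edge/edge ratio of the target graph.
#' @param seed integer seed controlling initialisation and dropout.
#' @return list of class `gae_config`.
#' @export
gae_config <- function(d, hidden = c(128L, 64L), dropout = 0.15,
                       epochs = 1000L, lr0 = 0.008, lr_decay_factor = 0.5,
                       lr_decay_every = 250L, pos_weight = "auto", seed = 1L) {
  stopifnot(d >= 1, dropout >= 0, dropout < 1, lr0 > 0, epochs >= 1,
            length(hidden) == 2L)
  if (!identical(pos_weight, "auto")) stopifnot(is.numeric(pos_weight), pos_weight > 0)
  structure(list(d = as.integer(d), hidden = as.integer(hidden),
                 dropout = dropout, epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 pos_weight = pos_weight, seed = seed),
            class = "gae_config")
}

#' Symmetric-normalised propagation matrix
#'
#' The GCN propagation operator with self-loops,
#' \eqn{\tilde D^{-1/2} (A + I) \tilde D^{-1/2}}, where \eqn{\tilde D} is the
#' degree matrix of \eqn{A + I}. Self-loops guarantee positive degrees, so
#' the operator is always defined.
#'
#' @param a symmetric adjacency with zero diagonal (matrix or `morpho_graph`).
#' @return sparse symmetric propagation matrix.
#' @export
normalize_adjacency <- function(a) {
  if (inherits(a, "morpho_graph")) a <- a$adjacency
  A <- Matrix::Matrix(a, sparse = TRUE)
  if (!Matrix::isSymmetric(A, tol = 1e-9)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(Matrix::diag(A) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  At <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  Matrix::Diagonal(x = dinv) %*% At %*% Matrix::Diagonal(x = dinv)
}

# ELU (alpha = 1): x for x > 0, expm1(x) below; expm1(pmin(x, 0)) vanishes
# on the positive branch, so both branches collapse into one expression.
# (R reference of the fused C kernel used in training.)
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

gae_init_params <- function(p, config) {
  h1 <- config$hidden[1L]; h2 <- config$hidden[2L]; d <- config$d
  list(W1 = glorot(p, h1), g1 = rep(1, h1), b1 = rep(0, h1),
       W2 = glorot(h1, h2), g2 = rep(1, h2), b2 = rep(0, h2),
       W3 = glorot(h2, d))
}

# Forward pass through the three GCN layers. Returns the latent matrix and,
# when `cache = TRUE`, every intermediate needed for backpropagation.
# `m1` short-circuits the first propagation (constant across epochs).
gcn_forward_full <- function(x, a_norm, params, config, training = FALSE,
                             cache = FALSE, m1 = NULL) {
  p <- config$dropout
  drop_mask <- function(nr, nc) {
    if (training && p > 0) (matrix(stats::runif(nr * nc), nr, nc) >= p) / (1 - p)
    else NULL
  }
  M1 <- if (is.null(m1)) as.matrix(a_norm %*% unclass(x)) else m1
  S1 <- M1 %*% params$W1
  L1 <- layer_norm_fwd_cpp(S1, params$g1, params$b1)
  e1 <- elu_fwd_cpp(L1$out)
  mk1 <- drop_mask(nrow(e1$y), ncol(e1$y))
  D1 <- if (is.null(mk1)) e1$y else e1$y * mk1

  M2 <- as.matrix(a_norm %*% D1)
  S2 <- M2 %*% params$W2
  L2 <- layer_norm_fwd_cpp(S2, params$g2, params$b2)
  e2 <- elu_fwd_cpp(L2$out)
  mk2 <- drop_mask(nrow(e2$y), ncol(e2$y))
  D2 <- if (is.null(mk2)) e2$y else e2$y * mk2

  M3 <- as.matrix(a_norm %*% D2)
  Z <- M3 %*% params$W3
  if (!cache) return(Z)
  list(Z = Z, M1 = M1, L1 = L1, e1 = e1, mk1 = mk1, D1 = D1,
       M2 = M2, L2 = L2, e2 = e2, mk2 = mk2, D2 = D2, M3 = M3)
}

#' Encode specimens with a (trained) GCN encoder
#'
#' Deterministic inference-mode forward pass: each hidden layer computes
#' propagate, linear map, layer normalisation, ELU (dropout disabled); the
#' final layer is a linear map after propagation, leaving the latent space
#' unconstrained.
#'
#' @param x corrected feature matrix (N x P).
#' @param a_norm propagation matrix from [normalize_adjacency()].
#' @param params parameter list (`W1,g1,b1,W2,g2,b2,W3`).
#' @param config a [gae_config()].
#' @param training enable dropout (training mode).
#' @return N x d latent matrix Z.
#' @export
gcn_forward <- function(x, a_norm, params, config, training = FALSE) {
  gcn_forward_full(x, a_norm, params, config, training = training, cache = FALSE)
}

#' Inner-product decoder
#'
#' Reconstructs edge probabilities from the latent embedding:
#' \eqn{\hat A = \sigma(Z Z^\top)} with \eqn{\sigma} the logistic sigmoid.
#' Symmetric by construction; entries lie strictly inside (0, 1).
#'
#' @param z N x d latent matrix.
#' @return N x N matrix of edge probabilities.
#' @export
decode_embedding <- function(z) {
  z <- as.matrix(z)
  1 / (1 + exp(-tcrossprod(z)))
}

#' Weighted binary cross-entropy reconstruction loss
#'
#' Mean over all off-diagonal ordered pairs of
#' \eqn{-[w^+ A_{ij} \log \hat A_{ij} + (1 - A_{ij}) \log(1 - \hat A_{ij})]}.
#' The positive-class weight compensates the extreme edge/non-edge imbalance
#' of sparse specimen graphs; `"auto"` sets it to the non-edge/edge ratio.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param a_hat reconstructed probabilities (N x N).
#' @param g target [morpho_graph()] (binary).
#' @param pos_weight positive-class weight (> 0) or `"auto"`.
#' @return scalar loss (>= 0).
#' @export
weighted_bce <- function(a_hat, g, pos_weight = "auto") {
  A <- as.matrix(g$adjacency)
  ah <- pmin(pmax(as.matrix(a_hat), 1e-7), 1 - 1e-7)
  stopifnot(all(dim(A) == dim(ah)))
  n <- nrow(A)
  pw <- resolve_pos_weight(pos_weight, g)
  off <- !diag(TRUE, n)
  -mean(pw * A[off] * log(ah[off]) + (1 - A[off]) * log(1 - ah[off]))
}

resolve_pos_weight <- function(pos_weight, g) {
  if (identical(pos_weight, "auto")) {
    n <- g$n_nodes
    e2 <- 2 * n_edges(g)
    if (e2 == 0) stop("auto pos_weight undefined on an edgeless graph", call. = FALSE)
    (n * (n - 1) - e2) / e2
  } else pos_weight
}

# Gradient of weighted_bce w.r.t. Z at A_hat = sigmoid(Z Z^T).
# dL/dU_ij = (1/M) [ (1 - A) sigma(u) - pw A (1 - sigma(u)) ] off-diagonal.
bce_grad_z <- function(z, a, pw) {
  n <- nrow(a)
  m_off <- n * (n - 1)
  u <- tcrossprod(z)
  s <- 1 / (1 + exp(-u))
  G <- ((1 - a) * s - pw * a * (1 - s)) / m_off
  diag(G) <- 0
  (G + t(G)) %*% z
}

#' Train the graph autoencoder
#'
#' Full-batch Adam on the weighted binary cross-entropy between
#' \eqn{\sigma(Z Z^\top)} and the observed k-NN adjacency, with the learning
#' rate stepped down by `lr_decay_factor` every `lr_decay_every` epochs.
#' Deterministic given `config$seed` (Glorot initialisation and the dropout
#' masks are drawn from a private RNG stream).
#'
#' @param x corrected feature matrix (specimens in rows).
#' @param g binary [morpho_graph()] built from the same specimens.
#' @param config a [gae_config()].
#' @return list of class `gae_fit`: `embedding` (inference-mode Z),
#'   `a_hat` (decoded probabilities), `trace` (per-epoch `loss` and `lr`,
#'   `final_loss`), `params`, `config`.
#' @export
gae_train <- function(x, g, config) {
  stopifnot(inherits(g, "morpho_graph"), inherits(config, "gae_config"))
  X <- unclass(x)
  if (nrow(X) != g$n_nodes) stop("feature matrix and graph disagree on N", call. = FALSE)
  if (config$d > ncol(X)) stop("latent dimension exceeds trait count", call. = FALSE)
  A <- as.matrix(g$adjacency)
  a_norm <- normalize_adjacency(g)
  pw <- resolve_pos_weight(config$pos_weight, g)

  with_seed(config$seed, {
    params <- gae_init_params(ncol(X), config)
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    losses <- numeric(config$epochs)
    lrs <- numeric(config$epochs)
    step <- 0L
    m1 <- as.matrix(a_norm %*% X)
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr0 * config$lr_decay_factor^((ep - 1L) %/% config$lr_decay_every)
      lrs[ep] <- lr
      fw <- gcn_forward_full(X, a_norm, params, config, training = TRUE,
                             cache = TRUE, m1 = m1)
      lg <- bce_loss_grad_cpp(tcrossprod(fw$Z), A, pw)
      loss <- lg$loss
      if (!is.finite(loss)) stop("non-finite loss at epoch ", ep, call. = FALSE)
      losses[ep] <- loss
      dZ <- 2 * (lg$grad %*% fw$Z)   # grad is symmetric: (G + G^T) Z = 2 G Z

      grads <- gcn_backward(dZ, fw, params, a_norm)
      step <- step + 1L
      for (nm in names(params)) {
        gr <- grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
        mh <- mstate[[nm]] / (1 - b1^step)
        vh <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    Z <- gcn_forward_full(X, a_norm, params, config, training = FALSE)
    structure(list(embedding = Z, a_hat = decode_embedding(Z),
                   trace = list(loss = losses, lr = lrs,
                                final_loss = losses[config$epochs]),
                   params = params, config = config),
              class = "gae_fit")
  })
}

#' Export a trained autoencoder as portable text files
#'
#' Writes every named weight array as CSV, a JSON snapshot of the training
#' configuration, and the latent embedding and reconstructed adjacency, so a
#' fit can be archived or inspected without R.
#'
#' @param fit a `gae_fit` from [gae_train()].
#' @param dir output directory (created if needed).
#' @export
write_gae_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "gae_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(fit$params)) {
    utils::write.csv(as.matrix(fit$params[[nm]]),
                     file.path(dir, paste0("weights_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(unclass(fit$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$embedding, file.path(dir, "embedding.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$a_hat, file.path(dir, "a_hat.csv"), row.names = FALSE)
  utils::write.csv(data.frame(epoch = seq_along(fit$trace$loss),
                              loss = fit$trace$loss, lr = fit$trace$lr),
                   file.path(dir, "training_trace.csv"), row.names = FALSE)
  invisible(dir)
}

gcn_backward <- function(dZ, fw, params, a_norm) {
  dW3 <- crossprod(fw$M3, dZ)
  dM3 <- tcrossprod(dZ, params$W3)
  dD2 <- as.matrix(a_norm %*% dM3)
  dE2 <- if (is.null(fw$mk2)) dD2 else dD2 * fw$mk2
  dL2 <- dE2 * fw$e2$grad
  ln2 <- layer_norm_bwd_cpp(dL2, fw$L2$xhat, fw$L2$inv, params$g2)
  dS2 <- ln2$dx
  dW2 <- crossprod(fw$M2, dS2)
  dM2 <- tcrossprod(dS2, params$W2)
  dD1 <- as.matrix(a_norm %*% dM2)
  dE1 <- if (is.null(fw$mk1)) dD1 else dD1 * fw$mk1
  dL1 <- dE1 * fw$e1$grad
  ln1 <- layer_norm_bwd_cpp(dL1, fw$L1$xhat, fw$L1$inv, params$g1)
  dW1 <- crossprod(fw$M1, ln1$dx)
  list(W1 = dW1, g1 = ln1$dg, b1 = ln1$db,
       W2 = dW2, g2 = ln2$dg, b2 = ln2$db,
       W3 = dW3)
}
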