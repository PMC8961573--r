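#' Multimodal autoencoder configuration
#'
#' Hyperparameters of the network-fusion autoencoder. One encoder branch per
#' input network (tanh, width `per_network_hidden`) feeds a shared joint
#' layer (tanh) and a sigmoid embedding layer of width `embedding_dim`; the
#' decoder mirrors the encoder with one sigmoid reconstruction head per
#' network. Training minimises the summed per-network binary cross-entropy
#' on min-max-scaled inputs with Adam; dropout is applied after the joint
#' layer during training only.
#'
#' @param per_network_hidden width of each per-network branch (default 256).
#' @param joint_hidden width of the shared joint layer (default 512).
#' @param embedding_dim width d of the embedding layer (default 128).
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size in drug rows (default 512; values at or
#'   above the number of drugs give full-batch training, which at desk scale
#'   is both faster and independent of row order).
#' @param learning_rate Adam step size (default 5e-3).
#' @param dropout_rate dropout probability after the joint layer (default 0.1).
#' @param seed integer seed controlling initialisation, batching and dropout.
#' @return list of class `mae_config`.
#' @export
mae_config <- function(per_network_hidden = 256L, joint_hidden = 512L,
                       embedding_dim = 128L, epochs = 200L, batch_size = 512L,
                       learning_rate = 5e-3, dropout_rate = 0.1, seed = 1L) {
  stopifnot(per_network_hidden >= 1, joint_hidden >= 1, embedding_dim >= 1,
            epochs >= 0, batch_size >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(per_network_hidden = as.integer(per_network_hidden),
                 joint_hidden = as.integer(joint_hidden),
                 embedding_dim = as.integer(embedding_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "mae_config")
}

#' Min-max scale PPMI matrices to the unit interval
#'
#' Each network's matrix is independently scaled so its minimum maps to 0 and
#' its maximum to 1 (sigmoid reconstruction heads require \[0, 1\] targets).
#' A constant matrix scales to all zeros with a warning. Scaling parameters
#' are recorded in the `scaling` attribute for reproducibility.
#'
#' @param ppmis list of matrices (typically from [embed_all()]).
#' @return list of scaled matrices with a `scaling` attribute
#'   (per-network min and range).
#' @export
scale_inputs <- function(ppmis) {
  stopifnot(length(ppmis) >= 1L)
  scaling <- vector("list", length(ppmis))
  out <- vector("list", length(ppmis))
  for (i in seq_along(ppmis)) {
    M <- as.matrix(ppmis[[i]])
    lo <- min(M)
    rg <- max(M) - lo
    if (rg == 0) {
      warning("network ", i, " is constant; scaled to zeros")
      out[[i]] <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    } else {
      out[[i]] <- (M - lo) / rg
    }
    scaling[[i]] <- c(min = lo, range = rg)
  }
  names(out) <- names(ppmis)
  attr(out, "scaling") <- scaling
  out
}

#' Build an untrained multimodal autoencoder
#'
#' @param cfg a [mae_config()].
#' @param n_networks number of input networks.
#' @param n_drugs input width (drugs per network row).
#' @return object of class `mae`: parameter list, config and dimensions.
#'   Initialisation is Glorot-uniform, seeded from `cfg$seed`.
#' @export
build_mae <- function(cfg, n_networks, n_drugs) {
  stopifnot(inherits(cfg, "mae_config"))
  G <- as.integer(n_networks)
  n <- as.integer(n_drugs)
  h1 <- cfg$per_network_hidden
  h2 <- cfg$joint_hidden
  d <- cfg$embedding_dim
  set.seed(derive_seed(cfg$seed, "mae-init"))
  params <- list()
  for (g in seq_len(G)) {
    params[[paste0("W_enc", g)]] <- glorot(n, h1)
    params[[paste0("b_enc", g)]] <- matrix(0, 1, h1)
  }
  params$W_joint <- glorot(G * h1, h2)
  params$b_joint <- matrix(0, 1, h2)
  params$W_emb <- glorot(h2, d)
  params$b_emb <- matrix(0, 1, d)
  params$W_demb <- glorot(d, h2)
  params$b_demb <- matrix(0, 1, h2)
  params$W_djoint <- glorot(h2, G * h1)
  params$b_djoint <- matrix(0, 1, G * h1)
  for (g in seq_len(G)) {
    params[[paste0("W_dec", g)]] <- glorot(h1, n)
    params[[paste0("b_dec", g)]] <- matrix(0, 1, n)
  }
  structure(list(params = params, config = cfg, n_networks = G, n_drugs = n,
                 trained = FALSE, history = NULL),
            class = "mae")
}

#' @export
print.mae <- function(x, ...) {
  cfg <- x$config
  cat("Multimodal autoencoder:", x$n_networks, "networks x", x$n_drugs,
      "drugs ->", cfg$embedding_dim, "features\n")
  cat("  branch", cfg$per_network_hidden, "| joint", cfg$joint_hidden,
      "| trained:", x$trained, "\n")
  if (!is.null(x$history))
    cat("  final loss:", format(utils::tail(x$history$loss, 1), digits = 6), "\n")
  invisible(x)
}

## forward pass; rows = a minibatch of drugs. mats: list of G matrices with
## the same rows selected. Hidden layers are tanh (zero-centred activations
## keep drug-level variation alive through the deep stack); the embedding
## layer and the reconstruction heads are sigmoid (features in [0, 1], BCE
## outputs). Returns activations needed for backprop.
mae_forward <- function(params, mats, G, dropout_mask = NULL) {
  A1 <- vector("list", G)
  for (g in seq_len(G)) {
    A1[[g]] <- tanh(sweep(mats[[g]] %*% params[[paste0("W_enc", g)]], 2,
                          params[[paste0("b_enc", g)]], "+"))
  }
  A1c <- do.call(cbind, A1)
  A2 <- tanh(sweep(A1c %*% params$W_joint, 2, params$b_joint, "+"))
  A2d <- if (is.null(dropout_mask)) A2 else A2 * dropout_mask
  A3 <- sigmoid(sweep(A2d %*% params$W_emb, 2, params$b_emb, "+"))
  A4 <- tanh(sweep(A3 %*% params$W_demb, 2, params$b_demb, "+"))
  A5 <- tanh(sweep(A4 %*% params$W_djoint, 2, params$b_djoint, "+"))
  Y <- vector("list", G)
  h1 <- ncol(A1[[1L]])
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * h1 + 1L):(g * h1)
    Y[[g]] <- sigmoid(sweep(A5[, cols, drop = FALSE] %*% params[[paste0("W_dec", g)]],
                            2, params[[paste0("b_dec", g)]], "+"))
  }
  list(A1c = A1c, A2 = A2, A2d = A2d, A3 = A3, A4 = A4, A5 = A5, Y = Y)
}

bce_mean <- function(target, pred) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

## summed per-network mean BCE for a set of rows
mae_batch_loss <- function(fw, mats, G) {
  per <- vapply(seq_len(G), function(g) bce_mean(mats[[g]], fw$Y[[g]]),
                numeric(1))
  list(total = sum(per), per_network = per)
}

#' Reconstruction loss of an autoencoder on given rows
#'
#' Summed per-network mean binary cross-entropy of the model's
#' reconstructions against the scaled inputs; used e.g. to compare a trained
#' model against its initialisation on held-out drug rows.
#'
#' @param model a `mae` (trained or not).
#' @param scaled list of scaled input matrices (see [scale_inputs()]).
#' @param rows optional integer subset of drug rows.
#' @return total loss (scalar) with per-network losses as an attribute.
#' @export
mae_loss <- function(model, scaled, rows = NULL) {
  G <- model$n_networks
  mats <- lapply(scaled, function(M) {
    M <- as.matrix(M)
    if (is.null(rows)) M else M[rows, , drop = FALSE]
  })
  fw <- mae_forward(model$params, mats, G)
  l <- mae_batch_loss(fw, mats, G)
  structure(l$total, per_network = l$per_network)
}

mae_backward <- function(params, fw, mats, G, dropout_mask = NULL) {
  grads <- lapply(params, function(p) p * 0)
  B <- nrow(fw$A3)
  h1 <- ncol(fw$A1c) / G
  n <- ncol(mats[[1L]])
  dA5 <- matrix(0, B, ncol(fw$A5))
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * h1 + 1L):(g * h1)
    dZ6 <- (fw$Y[[g]] - mats[[g]]) / (B * n) # d mean-BCE through sigmoid
    grads[[paste0("W_dec", g)]] <- crossprod(fw$A5[, cols, drop = FALSE], dZ6)
    grads[[paste0("b_dec", g)]] <- colSums(dZ6)
    dA5[, cols] <- tcrossprod(dZ6, params[[paste0("W_dec", g)]])
  }
  dZ5 <- dA5 * (1 - fw$A5^2) # tanh derivative
  grads$W_djoint <- crossprod(fw$A4, dZ5)
  grads$b_djoint <- colSums(dZ5)
  dZ4 <- tcrossprod(dZ5, params$W_djoint) * (1 - fw$A4^2)
  grads$W_demb <- crossprod(fw$A3, dZ4)
  grads$b_demb <- colSums(dZ4)
  dZ3 <- tcrossprod(dZ4, params$W_demb) * fw$A3 * (1 - fw$A3) # sigmoid embedding
  grads$W_emb <- crossprod(fw$A2d, dZ3)
  grads$b_emb <- colSums(dZ3)
  dA2d <- tcrossprod(dZ3, params$W_emb)
  if (!is.null(dropout_mask)) dA2d <- dA2d * dropout_mask
  dZ2 <- dA2d * (1 - fw$A2^2)
  grads$W_joint <- crossprod(fw$A1c, dZ2)
  grads$b_joint <- colSums(dZ2)
  dA1c <- tcrossprod(dZ2, params$W_joint)
  A1c <- fw$A1c
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * h1 + 1L):(g * h1)
    dZ1 <- dA1c[, cols, drop = FALSE] * (1 - A1c[, cols, drop = FALSE]^2)
    grads[[paste0("W_enc", g)]] <- crossprod(mats[[g]], dZ1)
    grads[[paste0("b_enc", g)]] <- colSums(dZ1)
  }
  grads
}

#' Train the multimodal autoencoder
#'
#' Minibatch Adam on the summed per-network binary cross-entropy. Fully
#' seeded: two runs from the same config reproduce the loss trajectory to
#' within floating-point determinism on one platform. Zero epochs return the
#' initialised model unchanged.
#'
#' @param model an untrained (or previously trained) `mae`.
#' @param scaled list of `n_networks` scaled matrices, all with the same
#'   drug rows (see [scale_inputs()]).
#' @return the model with `trained = TRUE` and a `history` data.frame of
#'   per-epoch total and per-network losses.
#' @export
train_mae <- function(model, scaled) {
  cfg <- model$config
  G <- model$n_networks
  stopifnot(length(scaled) == G)
  mats <- lapply(scaled, as.matrix)
  nr <- unique(vapply(mats, nrow, integer(1)))
  if (length(nr) != 1L) stop_input("all networks must have the same drug rows")
  if (cfg$epochs == 0L) return(model)
  params <- copy_params(model$params) # training updates happen in place
  opt <- adam_init(params)
  set.seed(derive_seed(cfg$seed, "mae-train"))
  loss_hist <- numeric(cfg$epochs)
  per_hist <- matrix(0, cfg$epochs, G)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(nr)
    starts <- seq(1L, nr, by = cfg$batch_size)
    tot <- 0
    per <- numeric(G)
    for (s in starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1L, nr)]
      batch <- lapply(mats, function(M) M[rows, , drop = FALSE])
      mask <- NULL
      if (cfg$dropout_rate > 0) {
        mask <- matrix(stats::rbinom(length(rows) * cfg$joint_hidden, 1L,
                                     1 - cfg$dropout_rate),
                       length(rows), cfg$joint_hidden) / (1 - cfg$dropout_rate)
      }
      fw <- mae_forward(params, batch, G, mask)
      l <- mae_batch_loss(fw, batch, G)
      if (!is.finite(l$total))
        stop("autoencoder loss became non-finite at epoch ", epoch,
             "; lower the learning rate")
      tot <- tot + l$total * length(rows)
      per <- per + l$per_network * length(rows)
      grads <- mae_backward(params, fw, batch, G, mask)
      upd <- adam_step(params, grads, opt, lr = cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    loss_hist[epoch] <- tot / nr
    per_hist[epoch, ] <- per / nr
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(cfg$epochs), loss = loss_hist)
  model$history_per_network <- per_hist
  model
}

#' Extract fused drug features from the embedding layer
#'
#' Deterministic forward pass (dropout disabled) through the encoder; row g
#' of the result is the fused low-dimensional representation of drug g across
#' all input networks.
#'
#' @param model a trained `mae`.
#' @param scaled the scaled input matrices used for training (or new rows in
#'   the same column space).
#' @return n_drugs x embedding_dim matrix of class `fused_features`; rownames
#'   are taken from the first input's rownames when present.
#' @export
extract_features <- function(model, scaled) {
  G <- model$n_networks
  mats <- lapply(scaled, as.matrix)
  fw <- mae_forward(model$params, mats, G)
  F <- fw$A3
  rownames(F) <- rownames(mats[[1L]])
  structure(F, class = c("fused_features", "matrix", "array"))
}
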