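#' Wasserstein variational autoencoder over disease-association rows
#'
#' The predictor consumes one row per disease: a binary vector over the drug
#' vocabulary marking known treatments. The encoder maps a row two ways —
#' a feature pooling `p(x) %*% F` (the association-weighted centroid of the
#' fused drug features) and a learned dense layer — concatenates both,
#' passes a tanh hidden layer with dropout, and emits the latent Gaussian
#' (mu, log sigma). A reparameterised sample z is decoded through a dense
#' layer to a length-d vector h, and drug scores are
#' `sigmoid(h %*% t(F) + b)`: the fused features condition both encoding and
#' decoding, so drugs with similar network profiles receive similar scores.
#'
#' @param latent_dim latent Gaussian dimension (default 32).
#' @param hidden encoder hidden width (default 256).
#' @param input_dense width of the learned dense encoding of the raw row
#'   (default 64).
#' @param dropout_rate dropout after the hidden layer, training only
#'   (default 0.1).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs training epochs (default 300).
#' @param pretrain_epochs optional warm-up epochs minimising the mean squared
#'   error between the pooled input features and the decoded feature vector
#'   h before the composite loss takes over (default 0).
#' @param seed integer seed (initialisation, dropout, latent sampling).
#' @return list of class `wvae_config`.
#' @export
wvae_config <- function(latent_dim = 32L, hidden = 256L, input_dense = 64L,
                        dropout_rate = 0.1, learning_rate = 1e-3,
                        epochs = 300L, pretrain_epochs = 0L, seed = 1L) {
  stopifnot(latent_dim >= 1, hidden >= 1, input_dense >= 1,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            epochs >= 0, pretrain_epochs >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden),
                 input_dense = as.integer(input_dense),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed)),
            class = "wvae_config")
}

#' @rdname wvae_config
#' @param n_drugs length of an association row.
#' @param features fused drug-feature matrix, `n_drugs` x d
#'   (see [extract_features()]); fixed during training.
#' @param cfg a [wvae_config()].
#' @return `build_wvae`: an untrained model of class `wvae`.
#' @export
build_wvae <- function(n_drugs, features, cfg = wvae_config()) {
  F <- as.matrix(features)
  if (nrow(F) != n_drugs)
    stop_input("features must have one row per drug (", n_drugs, ")")
  d <- ncol(F)
  set.seed(derive_seed(cfg$seed, "wvae-init"))
  params <- list(
    W_ed = glorot(n_drugs, cfg$input_dense), b_ed = matrix(0, 1, cfg$input_dense),
    W_h = glorot(d + cfg$input_dense, cfg$hidden), b_h = matrix(0, 1, cfg$hidden),
    W_mu = glorot(cfg$hidden, cfg$latent_dim), b_mu = matrix(0, 1, cfg$latent_dim),
    W_ls = glorot(cfg$hidden, cfg$latent_dim), b_ls = matrix(0, 1, cfg$latent_dim),
    W_dz = glorot(cfg$latent_dim, d), b_dz = matrix(0, 1, d),
    b_out = matrix(0, 1, n_drugs)
  )
  structure(list(params = params, config = cfg, features = F,
                 n_drugs = as.integer(n_drugs), d = d,
                 trained = FALSE, history = NULL),
            class = "wvae")
}

#' @export
print.wvae <- function(x, ...) {
  cat("Wasserstein VAE:", x$n_drugs, "drugs | features d =", x$d,
      "| latent", x$config$latent_dim, "| trained:", x$trained, "\n")
  if (!is.null(x$history))
    cat("  final loss:", format(utils::tail(x$history$loss, 1), digits = 6), "\n")
  invisible(x)
}

## deterministic = TRUE: z = mu, no dropout (inference path)
wvae_forward <- function(params, X, F, Pn, deterministic = TRUE,
                         dropout_mask = NULL, Eps = NULL) {
  Pool <- Pn %*% F
  He <- tanh(sweep(X %*% params$W_ed, 2, params$b_ed, "+"))
  Hc <- cbind(Pool, He)
  H <- tanh(sweep(Hc %*% params$W_h, 2, params$b_h, "+"))
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  Mu <- sweep(Hd %*% params$W_mu, 2, params$b_mu, "+")
  Ls_raw <- sweep(Hd %*% params$W_ls, 2, params$b_ls, "+")
  Ls <- pmin(pmax(Ls_raw, -8), 8) # keep exp(2*Ls) finite
  Z <- if (deterministic) Mu else Mu + exp(Ls) * Eps
  Hz <- tanh(sweep(Z %*% params$W_dz, 2, params$b_dz, "+"))
  S <- sweep(tcrossprod(Hz, F), 2, params$b_out, "+")
  list(Pool = Pool, He = He, Hc = Hc, H = H, Hd = Hd, Mu = Mu, Ls = Ls,
       Ls_open = abs(Ls_raw) < 8, Z = Z, Hz = Hz, S = S, Xhat = sigmoid(S))
}

## row-normalise a binary association matrix; all-zero rows become uniform
normalize_rows <- function(X, warn = FALSE) {
  rs <- rowSums(X)
  zero <- rs == 0
  if (any(zero) && warn)
    warning(sum(zero), " all-zero association row(s); using uniform distribution")
  Pn <- X / ifelse(rs == 0, 1, rs)
  if (any(zero)) Pn[zero, ] <- 1 / ncol(X)
  Pn
}

#' Train the Wasserstein VAE on an association matrix
#'
#' Full-batch Adam on the mean composite loss over disease rows
#' (`wasserstein + alpha * kl + aux_weight * bce`, see [loss_weights()]). In
#' sinkhorn mode the ground cost between drugs is the squared Euclidean
#' fused-feature distance scaled to unit mean, the entropic coupling is
#' solved in batch across diseases with warm-started scalings, and its dual
#' potentials provide the gradient of the transport cost. Seeded and
#' deterministic on one platform.
#'
#' @param model an untrained `wvae` (see [build_wvae()]).
#' @param X binary disease x drug association matrix (rows follow
#'   `rownames`, columns follow the drug vocabulary of the features).
#' @param weights a [loss_weights()].
#' @param epochs overrides `model$config$epochs` when given.
#' @return the trained model, with a `history` data.frame of per-epoch mean
#'   total, wasserstein, kl and auxiliary losses.
#' @export
train_wvae <- function(model, X, weights = loss_weights(), epochs = NULL) {
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  X <- as.matrix(X)
  if (ncol(X) != model$n_drugs) stop_input("X must have one column per drug")
  if (!all(X %in% c(0, 1))) stop_input("X must be binary")
  F <- model$features
  n <- model$n_drugs
  B <- nrow(X)
  Pn <- normalize_rows(X, warn = TRUE)
  sink <- NULL
  if (weights$ot_mode == "sinkhorn") {
    Cn <- feature_cost(F)
    Cn <- Cn / mean(Cn)
    # kernel floor: keeps far-apart drug pairs reachable at astronomically
    # low weight instead of underflowing to an unreachable 0, which would
    # let the matrix scalings blow up to Inf/NaN
    K <- pmax(exp(-Cn / weights$sinkhorn_epsilon), 1e-60)
    sink <- list(K = K, KC = K * Cn, V = NULL, Pt = t(Pn))
  }
  params <- copy_params(model$params) # training updates happen in place
  opt <- adam_init(params)
  set.seed(derive_seed(cfg$seed, "wvae-train"))
  if (cfg$pretrain_epochs > 0L && epochs > 0L) {
    params <- wvae_pretrain(params, X, Pn, F, cfg)
  }
  hist <- matrix(NA_real_, epochs, 4,
                 dimnames = list(NULL, c("loss", "wasserstein", "kl", "aux")))
  for (epoch in seq_len(epochs)) {
    mask <- NULL
    if (cfg$dropout_rate > 0) {
      mask <- matrix(stats::rbinom(B * cfg$hidden, 1L, 1 - cfg$dropout_rate),
                     B, cfg$hidden) / (1 - cfg$dropout_rate)
    }
    Eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    fw <- wvae_forward(params, X, F, Pn, deterministic = FALSE,
                       dropout_mask = mask, Eps = Eps)
    Xhat <- fw$Xhat
    # --- loss components (means over disease rows)
    p_clip <- pmin(pmax(Xhat, 1e-7), 1 - 1e-7)
    aux_rows <- -rowSums(X * log(p_clip) + (1 - X) * log(1 - p_clip))
    kl_rows <- rowSums(-0.5 * (1 + 2 * fw$Ls - fw$Mu^2 - exp(2 * fw$Ls)))
    if (weights$ot_mode == "sinkhorn") {
      S_hat <- rowSums(Xhat)
      Qt <- t(Xhat / S_hat)
      sb <- sinkhorn_batch(sink$K, sink$KC, sink$Pt, Qt,
                           weights$sinkhorn_epsilon, V = sink$V)
      sink$V <- sb$V
      w_rows <- sb$costs
      g <- t(sb$g) # B x n dual potentials on the reconstruction side
      g_dot <- rowSums(g * t(Qt))
      dW_dXhat <- (g - g_dot) / S_hat
    } else {
      w_rows <- rowMeans((X - Xhat)^2)
      dW_dXhat <- 2 * (Xhat - X) / n
    }
    total <- mean(w_rows + weights$alpha * kl_rows + weights$aux_weight * aux_rows)
    if (!is.finite(total))
      stop("WVAE loss became non-finite at epoch ", epoch,
           "; lower the learning rate or raise sinkhorn_epsilon")
    hist[epoch, ] <- c(total, mean(w_rows), mean(kl_rows), mean(aux_rows))
    # --- backward
    dS <- (weights$aux_weight * (Xhat - X) +
             dW_dXhat * Xhat * (1 - Xhat)) / B
    grads <- wvae_backward(params, fw, X, F, dS, Eps, mask,
                           alpha = weights$alpha, B = B)
    upd <- adam_step(params, grads, opt, lr = cfg$learning_rate)
    params <- upd$params
    opt <- upd$state
  }
  model$params <- params
  model$trained <- epochs > 0L
  model$history <- data.frame(epoch = seq_len(epochs), hist)
  model
}

wvae_backward <- function(params, fw, X, F, dS, Eps, mask, alpha, B) {
  grads <- lapply(params, function(p) p * 0)
  grads$b_out <- colSums(dS)
  dHz_pre <- (dS %*% F) * (1 - fw$Hz^2)
  grads$W_dz <- t(fw$Z) %*% dHz_pre
  grads$b_dz <- colSums(dHz_pre)
  dZ <- dHz_pre %*% t(params$W_dz)
  dMu <- dZ + (alpha / B) * fw$Mu
  dLs <- (dZ * Eps * exp(fw$Ls) + (alpha / B) * (exp(2 * fw$Ls) - 1)) *
    fw$Ls_open # clamped entries get no gradient
  grads$W_mu <- t(fw$Hd) %*% dMu
  grads$b_mu <- colSums(dMu)
  grads$W_ls <- t(fw$Hd) %*% dLs
  grads$b_ls <- colSums(dLs)
  dHd <- dMu %*% t(params$W_mu) + dLs %*% t(params$W_ls)
  if (!is.null(mask)) dHd <- dHd * mask
  dH_pre <- dHd * (1 - fw$H^2)
  grads$W_h <- t(fw$Hc) %*% dH_pre
  grads$b_h <- colSums(dH_pre)
  dHc <- dH_pre %*% t(params$W_h)
  d <- ncol(fw$Pool)
  dHe_pre <- dHc[, (d + 1):ncol(dHc), drop = FALSE] * (1 - fw$He^2)
  grads$W_ed <- t(X) %*% dHe_pre
  grads$b_ed <- colSums(dHe_pre)
  grads
}

## optional warm-up: align the decoded feature vector h with the pooled
## input features by mean squared error (drug-feature reconstruction)
wvae_pretrain <- function(params, X, Pn, F, cfg) {
  opt <- adam_init(params)
  B <- nrow(X)
  for (epoch in seq_len(cfg$pretrain_epochs)) {
    Eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    fw <- wvae_forward(params, X, F, Pn, deterministic = FALSE, Eps = Eps)
    dHz <- (fw$Hz - fw$Pool) / length(fw$Pool) # d of mse_loss * 2
    dHz_pre <- dHz * (1 - fw$Hz^2)
    grads <- lapply(params, function(p) p * 0)
    grads$W_dz <- t(fw$Z) %*% dHz_pre
    grads$b_dz <- colSums(dHz_pre)
    dZ <- dHz_pre %*% t(params$W_dz)
    grads$W_mu <- t(fw$Hd) %*% dZ
    grads$b_mu <- colSums(dZ)
    dLs <- dZ * Eps * exp(fw$Ls) * fw$Ls_open
    grads$W_ls <- t(fw$Hd) %*% dLs
    grads$b_ls <- colSums(dLs)
    dHd <- dZ %*% t(params$W_mu) + dLs %*% t(params$W_ls)
    dH_pre <- dHd * (1 - fw$H^2)
    grads$W_h <- t(fw$Hc) %*% dH_pre
    grads$b_h <- colSums(dH_pre)
    dHc <- dH_pre %*% t(params$W_h)
    d <- ncol(fw$Pool)
    dHe_pre <- dHc[, (d + 1):ncol(dHc), drop = FALSE] * (1 - fw$He^2)
    grads$W_ed <- t(X) %*% dHe_pre
    grads$b_ed <- colSums(dHe_pre)
    upd <- adam_step(params, grads, opt, lr = cfg$learning_rate)
    params <- upd$params
    opt <- upd$state
  }
  params
}

#' Score drugs for disease rows
#'
#' Deterministic inference: dropout off and z fixed to the posterior mean.
#' Scores lie in (0, 1); each disease's drugs are ranked by descending
#' score, ties broken by vocabulary order. With `mask_known = TRUE` the
#' drugs already positive in the query are flagged so novel candidates can
#' be read off the top of the table.
#'
#' @param object a trained `wvae`.
#' @param x_query binary association row (or matrix of rows; rownames are
#'   used as disease identifiers).
#' @param mask_known flag known positives in the output (default `TRUE`).
#' @param drugs optional drug identifiers for the columns.
#' @param ... unused.
#' @return a `prediction_table` data.frame with columns `disease_id`,
#'   `drug_id`, `score`, `rank`, `known`.
#' @export
predict.wvae <- function(object, x_query, mask_known = TRUE, drugs = NULL, ...) {
  X <- if (is.matrix(x_query)) x_query else matrix(x_query, nrow = 1)
  if (ncol(X) != object$n_drugs) stop_input("query must have one entry per drug")
  drugs <- drugs %||% colnames(X) %||% rownames(object$features) %||%
    paste0("drug", seq_len(object$n_drugs))
  ids <- rownames(X) %||% paste0("disease", seq_len(nrow(X)))
  Pn <- normalize_rows(X, warn = FALSE)
  fw <- wvae_forward(object$params, X, object$features, Pn, deterministic = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    sc <- fw$Xhat[i, ]
    ord <- order(-sc, seq_along(sc))
    data.frame(disease_id = ids[i], drug_id = drugs[ord], score = sc[ord],
               rank = seq_along(sc),
               known = if (mask_known) X[i, ord] == 1 else FALSE,
               row.names = NULL)
  }))
  class(out) <- c("prediction_table", "data.frame")
  out
}
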