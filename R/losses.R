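#' Loss components of the association predictor
#'
#' The association predictor is trained with a composite loss:
#' `total = wasserstein + alpha * kl + aux_weight * bce`. The Wasserstein
#' term compares the observed and reconstructed disease rows as
#' distributions over drugs under a ground cost in fused-feature space; the
#' Kullback-Leibler term regularises the latent Gaussian toward a standard
#' normal; the auxiliary binary cross-entropy anchors individual drug scores
#' to the known associations.
#'
#' @param D,D_hat numeric arrays of equal shape.
#' @return `mse_loss`: mean over entries of `(D - D_hat)^2`, halved.
#' @export
mse_loss <- function(D, D_hat) {
  if (length(D) != length(D_hat)) stop_input("D and D_hat must match in shape")
  mean((D - D_hat)^2) / 2
}

#' @rdname mse_loss
#' @param mu,sigma latent Gaussian mean and standard deviation vectors
#'   (`sigma` strictly positive).
#' @return `kl_regularization`: `sum(-0.5 * (1 + log(sigma^2) - mu^2 -
#'   sigma^2))`, the KL divergence from N(mu, sigma) to N(0, 1); non-negative
#'   and zero only at mu = 0, sigma = 1.
#' @export
kl_regularization <- function(mu, sigma) {
  if (any(sigma <= 0)) stop_input("sigma must be strictly positive")
  if (length(mu) != length(sigma)) stop_input("mu and sigma must match in length")
  sum(-0.5 * (1 + 2 * log(sigma) - mu^2 - sigma^2))
}

#' @rdname mse_loss
#' @param x binary observed row; `x_hat` predicted scores, clipped into
#'   `[1e-7, 1 - 1e-7]` before the logs.
#' @return `auxiliary_loss`: summed binary cross-entropy
#'   `-sum(x * log(x_hat) + (1 - x) * log(1 - x_hat))`.
#' @export
auxiliary_loss <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop_input("x and x_hat must match in length")
  p <- pmin(pmax(x_hat, 1e-7), 1 - 1e-7)
  -sum(x * log(p) + (1 - x) * log(1 - p))
}

#' Weights and mode of the composite loss
#'
#' @param alpha weight of the KL regularisation (default 0.1).
#' @param aux_weight weight of the auxiliary cross-entropy (default 0.1).
#' @param sinkhorn_epsilon entropic regularisation of the transport solver
#'   (default 0.05; inside training it applies to the ground cost scaled to
#'   unit mean, making it scale-free).
#' @param ot_mode `"sinkhorn"` (default): full optimal-transport coupling
#'   with fused-feature ground cost; `"diagonal"`: identity coupling,
#'   reducing the Wasserstein term to the mean squared difference of the two
#'   rows (the same-index reading of the geometry distance).
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.1, aux_weight = 0.1,
                         sinkhorn_epsilon = 0.05,
                         ot_mode = c("sinkhorn", "diagonal")) {
  ot_mode <- match.arg(ot_mode)
  stopifnot(alpha >= 0, aux_weight >= 0)
  if (ot_mode == "sinkhorn" && sinkhorn_epsilon <= 0)
    stop_input("sinkhorn_epsilon must be positive in sinkhorn mode")
  structure(list(alpha = alpha, aux_weight = aux_weight,
                 sinkhorn_epsilon = sinkhorn_epsilon, ot_mode = ot_mode),
            class = "loss_weights")
}

## normalise a non-negative row to a distribution; all-zero -> uniform
as_distribution <- function(x, warn = TRUE) {
  s <- sum(x)
  if (s <= 0) {
    if (warn) warning("all-zero row; falling back to the uniform distribution")
    return(rep(1 / length(x), length(x)))
  }
  x / s
}

#' Wasserstein reconstruction loss between two disease rows
#'
#' In `"sinkhorn"` mode the observed and reconstructed rows are normalised
#' to distributions over drugs; the ground cost between drugs i and j is the
#' squared Euclidean distance of their fused-feature rows, and the loss is
#' the transport cost `sum(gamma * cost)` of the entropic optimal coupling.
#' In `"diagonal"` mode the coupling is fixed to the identity, and the loss
#' reduces to `mean((x - x_hat)^2)`.
#'
#' @param x,x_hat non-negative rows of equal length (one drug per entry).
#' @param features fused drug-feature matrix (drugs x d); only used in
#'   sinkhorn mode.
#' @param weights a [loss_weights()].
#' @param cost optional precomputed ground-cost matrix overriding `features`.
#' @return non-negative scalar.
#' @export
wasserstein_loss <- function(x, x_hat, features = NULL,
                             weights = loss_weights(), cost = NULL) {
  if (length(x) != length(x_hat)) stop_input("x and x_hat must match in length")
  if (any(x < 0) || any(x_hat < 0)) stop_input("rows must be non-negative")
  if (weights$ot_mode == "diagonal") return(mean((x - x_hat)^2))
  if (is.null(cost)) {
    if (is.null(features)) stop_input("sinkhorn mode needs features or cost")
    cost <- feature_cost(features)
  }
  p <- as_distribution(x)
  q <- as_distribution(x_hat)
  sinkhorn_plan(p, q, cost, weights$sinkhorn_epsilon, tol = 1e-9)$cost
}

#' @rdname wasserstein_loss
#' @return `feature_cost`: drugs x drugs squared-Euclidean distance matrix
#'   between fused-feature rows.
#' @export
feature_cost <- function(features) {
  F <- as.matrix(features)
  sq <- rowSums(F^2)
  C <- outer(sq, sq, "+") - 2 * tcrossprod(F)
  C[C < 0] <- 0
  diag(C) <- 0
  C
}

#' @rdname mse_loss
#' @param z list with elements `mu` and `sigma` (the latent Gaussian).
#' @param features fused feature matrix for the Wasserstein ground cost.
#' @param weights a [loss_weights()].
#' @return `total_loss`: `wasserstein + alpha * kl + aux_weight * bce`.
#' @export
total_loss <- function(x, x_hat, z, features = NULL,
                       weights = loss_weights()) {
  w <- wasserstein_loss(x, x_hat, features, weights)
  kl <- if (weights$alpha > 0) kl_regularization(z$mu, z$sigma) else 0
  aux <- if (weights$aux_weight > 0) auxiliary_loss(x, x_hat) else 0
  w + weights$alpha * kl + weights$aux_weight * aux
}
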