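#' Entropically regularised optimal transport (Sinkhorn)
#'
#' Solves the discrete optimal-transport problem between two distributions P
#' and Q under a ground cost, with entropic regularisation `epsilon`, by
#' log-domain Sinkhorn iterations (numerically stable down to small
#' `epsilon`). The returned coupling's row sums reproduce P and its column
#' sums reproduce Q (within `tol`); as `epsilon` decreases the transport cost
#' `sum(gamma * cost)` approaches the exact linear-program optimum.
#'
#' @param P,Q non-negative vectors summing to 1 (within 1e-9).
#' @param cost non-negative finite cost matrix, `length(P)` x `length(Q)`.
#' @param epsilon entropic regularisation strength (> 0).
#' @param tol convergence tolerance on the marginal error (default 1e-9).
#' @param max_iter iteration cap (default 1000); non-convergence warns and
#'   returns the best iterate.
#' @return object of class `transport_plan`: list with `gamma` (the
#'   coupling), `P`, `Q`, `cost` (the transport cost `sum(gamma * cost)`),
#'   dual potentials `f`, `g`, `iterations` and `converged`.
#' @examples
#' pl <- sinkhorn_plan(c(.5, .5), c(.5, .5), matrix(c(0, 1, 1, 0), 2), 0.01)
#' pl$cost # ~0: mass stays on the zero-cost diagonal
#' @export
sinkhorn_plan <- function(P, Q, cost, epsilon, tol = 1e-9, max_iter = 1000L) {
  P <- as.numeric(P); Q <- as.numeric(Q)
  if (abs(sum(P) - 1) > 1e-9 || abs(sum(Q) - 1) > 1e-9)
    stop_input("P and Q must sum to 1")
  if (any(P < 0) || any(Q < 0)) stop_input("P and Q must be non-negative")
  cost <- as.matrix(cost)
  if (any(!is.finite(cost)) || any(cost < 0))
    stop_input("cost must be finite and non-negative")
  if (nrow(cost) != length(P) || ncol(cost) != length(Q))
    stop_input("cost must be length(P) x length(Q)")
  if (epsilon <= 0) stop_input("epsilon must be positive")
  logP <- log(P) # -Inf on empty support is handled throughout
  logQ <- log(Q)
  f <- numeric(length(P))
  g <- numeric(length(Q))
  f[P == 0] <- -Inf
  g[Q == 0] <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # f_i <- eps * (logP_i - LSE_j((g_j - C_ij)/eps))
    f_new <- epsilon * (logP - logsumexp_rows(sweep(-cost, 2, g, "+") / epsilon))
    f_new[P == 0] <- -Inf
    g <- epsilon * (logQ - logsumexp_rows(t(sweep(-cost, 1, f_new, "+")) / epsilon))
    g[Q == 0] <- -Inf
    f <- f_new
    lg <- sweep(sweep(-cost, 1, f, "+"), 2, g, "+") / epsilon
    lg[!is.finite(lg)] <- -Inf
    gamma <- exp(lg)
    err <- max(abs(rowSums(gamma) - P), abs(colSums(gamma) - Q))
    if (err < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(rowSums(gamma) - P), abs(colSums(gamma) - Q)) > 1e-6)
    warning("Sinkhorn did not reach tolerance ", tol, " in ", max_iter,
            " iterations; returning best iterate")
  structure(list(gamma = gamma, P = P, Q = Q,
                 cost = sum(gamma * cost), f = f, g = g,
                 iterations = it, converged = converged),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("Transport plan:", length(x$P), "->", length(x$Q),
      "| cost", format(x$cost, digits = 6),
      "|", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

## Batched scaling-form Sinkhorn used inside WVAE training. K = exp(-C/eps)
## and KC = K * C are precomputed once per fit (the ground cost is fixed by
## the fused features). Pt, Qt are n x B column-distributions. Returns
## transport costs, dual potentials g for the Q side, and the scalings for
## warm-starting the next epoch.
sinkhorn_batch <- function(K, KC, Pt, Qt, epsilon, V = NULL,
                           tol = 1e-6, max_iter = 200L) {
  if (is.null(V)) V <- matrix(1, nrow(Qt), ncol(Qt))
  U <- matrix(0, nrow(Pt), ncol(Pt))
  for (it in seq_len(max_iter)) {
    KV <- K %*% V
    U <- ifelse(Pt > 0, Pt / KV, 0)
    KU <- crossprod(K, U) # K symmetric in our use, but stay general
    V <- Qt / KU
    if (any(!is.finite(V))) V[!is.finite(V)] <- 1 # restart degenerate scalings
    if (it %% 5L == 0L || it == max_iter) {
      err <- max(abs(V * KU - Qt), abs(U * (K %*% V) - Pt))
      if (is.finite(err) && err < tol) break
    }
  }
  costs <- colSums(U * (KC %*% V))
  g <- epsilon * log(V)
  # fix the gauge of the returned scalings: (u, v) is only defined up to a
  # per-column constant, and warm-starting across epochs otherwise lets that
  # constant drift until it over- or underflows
  smax <- apply(V, 2L, max)
  smax[!is.finite(smax) | smax <= 0] <- 1
  V <- sweep(V, 2L, smax, "/")
  list(costs = costs, g = g, V = V, iterations = it)
}
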