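## Independent brute-force oracles used to validate the package's
## implementations. Each is written from the definition, without reusing any
## code path it checks.

## full dynamic-programming Smith-Waterman with affine gaps
## (gap of length L costs open + L * ext)
oracle_sw <- function(a, b, sub, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  FF <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(E[i, j - 1L] - ext, H[i, j - 1L] - open - ext)
      FF[i, j] <- max(FF[i - 1L, j] - ext, H[i - 1L, j] - open - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub[A[i - 1L], B[j - 1L]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

oracle_sw_similarity <- function(a, b, sub, open = 10, ext = 1) {
  saa <- oracle_sw(a, a, sub, open, ext)
  sbb <- oracle_sw(b, b, sub, open, ext)
  if (saa <= 0 || sbb <= 0) return(0)
  max(oracle_sw(a, b, sub, open, ext), 0) / sqrt(saa * sbb)
}

## elementwise PPMI from the definition
oracle_ppmi <- function(C) {
  total <- sum(C)
  out <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) {
    for (j in seq_len(ncol(C))) {
      if (C[i, j] > 0) {
        v <- log(C[i, j] * total / (sum(C[i, ]) * sum(C[, j])))
        out[i, j] <- max(v, 0)
      }
    }
  }
  out
}

## Wang S-values by exhaustive path enumeration over all ancestor paths
oracle_wang_svalues <- function(term, parents, weights) {
  sv <- new.env()
  assign(term, 1, envir = sv)
  walk <- function(t, val) {
    ps <- parents[[t]]
    if (is.null(ps)) return(invisible())
    ws <- weights[[t]]
    for (k in seq_along(ps)) {
      v <- val * ws[k]
      cur <- mget(ps[k], envir = sv, ifnotfound = list(-Inf))[[1L]]
      if (v > cur) assign(ps[k], v, envir = sv)
      walk(ps[k], v)
    }
  }
  walk(term, 1)
  unlist(as.list(sv))
}

oracle_wang_sim <- function(t1, t2, parents, weights) {
  s1 <- oracle_wang_svalues(t1, parents, weights)
  s2 <- oracle_wang_svalues(t2, parents, weights)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0L) return(0)
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

## AUROC by exhaustive positive/negative pair counting, ties as 1/2
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## exact small transportation LP by enumerating basic feasible solutions:
## every vertex of the polytope has at most m + n - 1 basic cells
oracle_transport_lp <- function(P, Q, cost) {
  m <- length(P)
  n <- length(Q)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  nb <- m + n - 1L
  best <- Inf
  combs <- utils::combn(nrow(cells), nb)
  A_eq <- rbind(
    t(vapply(seq_len(m), function(i) as.numeric(cells$i == i),
             numeric(nrow(cells)))),
    t(vapply(seq_len(n), function(j) as.numeric(cells$j == j),
             numeric(nrow(cells))))
  )
  b_eq <- c(P, Q)
  for (k in seq_len(ncol(combs))) {
    sel <- combs[, k]
    A <- A_eq[, sel, drop = FALSE]
    x <- tryCatch(qr.solve(A, b_eq, tol = 1e-12), error = function(e) NULL)
    if (is.null(x)) next
    if (any(x < -1e-9)) next
    if (max(abs(A %*% x - b_eq)) > 1e-8) next
    v <- sum(x * cost[cbind(cells$i[sel], cells$j[sel])])
    best <- min(best, v)
  }
  best
}

## small shared fixture: a tiny bundle that exercises every modality fast
tiny_bundle <- function(seed = 7L) {
  generate_bundle(synthetic_config(n_drugs = 36L, n_genes = 48L,
                                   n_side_effects = 60L, n_diseases = 12L,
                                   n_clusters = 6L, seed = seed))
}
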