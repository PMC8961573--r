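#' Row-stochastic transition matrix of a network
#'
#' Normalises a non-negative adjacency/similarity matrix so each row sums to
#' one. All-zero rows (isolated drugs) become the uniform distribution,
#' keeping the matrix stochastic.
#'
#' @param net a [homogeneous_network()] or non-negative square matrix.
#' @return n x n row-stochastic matrix.
#' @export
transition_matrix <- function(net) {
  A <- as.matrix(net)
  if (nrow(A) != ncol(A)) stop_input("adjacency must be square")
  if (any(A < 0)) stop_input("adjacency entries must be non-negative")
  rs <- rowSums(A)
  zero <- rs == 0
  M <- A / ifelse(rs == 0, 1, rs)
  if (any(zero)) M[zero, ] <- 1 / ncol(A)
  M
}

#' Random-walk-with-restart co-occurrence matrix
#'
#' Deterministic closed-form propagation of the restart walk
#' `p_k = omega * p_{k-1} %*% M + (1 - omega) * p_0`: for each start drug i,
#' `p_0` is the one-hot vector at i and row i of the co-occurrence matrix C
#' is the sum of the walk distributions over steps 1..k. Probability mass is
#' conserved, so every row of C sums to the walk length k. No vertex
#' sequences are sampled; the propagation computes the walk's co-occurrence
#' expectations exactly.
#'
#' @param M row-stochastic transition matrix (see [transition_matrix()]).
#' @param omega continue probability in \[0, 1\] (default 0.5).
#' @param walk_length number of steps k >= 1 (default 3).
#' @return n x n co-occurrence matrix with row sums `walk_length`.
#' @examples
#' M <- transition_matrix(matrix(c(0, 2, 2, 0), 2))
#' rwr_cooccurrence(M, omega = 1, walk_length = 2) # p1 + p2 per start node
#' @export
rwr_cooccurrence <- function(M, omega = 0.5, walk_length = 3L) {
  if (omega < 0 || omega > 1) stop_input("omega must lie in [0, 1]")
  walk_length <- as.integer(walk_length)
  if (walk_length < 1L) stop_input("walk_length must be >= 1")
  n <- nrow(M)
  if (max(abs(rowSums(M) - 1)) > 1e-9) stop_input("M must be row-stochastic")
  P <- diag(n) # p_0 for every start node at once (rows = start nodes)
  C <- matrix(0, n, n)
  restart <- (1 - omega) * diag(n)
  for (step in seq_len(walk_length)) {
    P <- omega * (P %*% M) + restart
    C <- C + P
  }
  dimnames(C) <- dimnames(as.matrix(M))
  C
}

#' Positive pointwise mutual information of a co-occurrence matrix
#'
#' Each entry compares the observed co-occurrence with the product of its
#' row and column marginals:
#' `PPMI(i, j) = max(log(C(i, j) * T / (rowsum_i * colsum_j)), 0)` with T the
#' total mass of C. Zero co-occurrences stay 0 (the limit convention), so the
#' result is finite, non-negative, and invariant to global rescaling of C.
#'
#' @param C non-negative co-occurrence matrix with positive total mass.
#' @param source_kind label recorded on the result.
#' @return `ppmi_matrix`: the PPMI matrix with a `source_kind` attribute.
#' @examples
#' ppmi(matrix(c(2, 0, 0, 2), 2)) # diagonal log 2, off-diagonal 0
#' @export
ppmi <- function(C, source_kind = "network") {
  C <- as.matrix(C)
  if (any(C < 0)) stop_input("co-occurrence entries must be non-negative")
  total <- sum(C)
  if (total <= 0) stop_input("co-occurrence matrix has no mass")
  rs <- rowSums(C)
  cs <- colSums(C)
  P <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  nz <- C > 0
  P[nz] <- pmax(log(C[nz] * total / (outer(rs, cs)[nz])), 0)
  structure(P, source_kind = source_kind,
            class = c("ppmi_matrix", "matrix", "array"))
}

#' Embed all nine drug networks as PPMI matrices
#'
#' Homogeneous networks go through transition-matrix normalisation,
#' random-walk co-occurrence and PPMI. Bipartite networks are first collapsed
#' to drug-drug Jaccard networks ([jaccard_network()]) and then, by default,
#' follow the same walk + PPMI route (set `rwr_bipartite = FALSE` to take
#' PPMI of the Jaccard matrix directly).
#'
#' @param networks list of [homogeneous_network()] / [bipartite_network()]
#'   objects sharing one vocabulary.
#' @param omega,walk_length random-walk parameters (defaults 0.5 and 3).
#' @param rwr_bipartite logical; run the random walk on Jaccard-collapsed
#'   bipartite networks too (default `TRUE`).
#' @param drop_self exclude each drug's self-co-occurrence before PPMI
#'   (default `TRUE`). The restart walk concentrates most of its mass on the
#'   start vertex; left in place, that mass inflates the marginals so far
#'   that the off-diagonal association ratios of dense networks fall below
#'   independence and clip to zero. Dropping the diagonal keeps the PPMI on
#'   cross-drug co-occurrence only.
#' @return named list of [ppmi()] matrices, one per input, in input order.
#' @export
embed_all <- function(networks, omega = 0.5, walk_length = 3L,
                      rwr_bipartite = TRUE, drop_self = TRUE) {
  stopifnot(length(networks) >= 1L)
  vocabs <- lapply(networks, net_vocab)
  ref <- vocabs[[1L]]
  same <- vapply(vocabs, function(v) identical(as.character(v), as.character(ref)),
                 logical(1))
  if (!all(same)) stop_input("all networks must share one drug vocabulary")
  out <- lapply(networks, function(net) {
    kind <- net_kind(net) %||% "network"
    if (inherits(net, "bipartite_network")) {
      net <- jaccard_network(net)
      if (!rwr_bipartite) {
        J <- as.matrix(net)
        if (drop_self) diag(J) <- 0
        return(ppmi(J, source_kind = kind))
      }
    }
    C <- rwr_cooccurrence(transition_matrix(net), omega, walk_length)
    if (drop_self) diag(C) <- 0
    ppmi(C, source_kind = kind)
  })
  names(out) <- vapply(networks, function(n) net_kind(n) %||% "network",
                       character(1))
  out
}
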