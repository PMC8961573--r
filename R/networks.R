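#' Network containers
#'
#' Two light containers carry the nine input networks. A homogeneous network
#' is an n x n non-negative drug-drug matrix (similarity networks additionally
#' have unit diagonal and entries in \[0, 1\]); a bipartite network is an
#' n x m binary incidence matrix of drugs against some entity set (genes,
#' side effects or diseases).
#'
#' @param matrix numeric matrix; rows follow `vocab` order.
#' @param vocab a [drug_vocabulary()].
#' @param kind short label of the measure that produced the network.
#' @param similarity logical; if `TRUE`, entries must lie in \[0, 1\]. Rows of
#'   drugs with no data in the underlying modality may be all-zero (including
#'   the diagonal), encoding "no evidence".
#' @return `homogeneous_network`: the matrix with `vocab`/`kind` attributes.
#' @export
homogeneous_network <- function(matrix, vocab, kind = "similarity",
                                similarity = TRUE) {
  n <- length(vocab)
  if (!is.matrix(matrix) || nrow(matrix) != n || ncol(matrix) != n)
    stop_input("matrix must be ", n, " x ", n)
  if (any(!is.finite(matrix))) stop_input("matrix entries must be finite")
  if (any(matrix < 0)) stop_input("matrix entries must be non-negative")
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop_input("matrix must be symmetric")
  if (similarity && any(matrix > 1 + 1e-12))
    stop_input("similarity entries must lie in [0, 1]")
  dimnames(matrix) <- list(as.character(vocab), as.character(vocab))
  structure(matrix, vocab = vocab, kind = kind,
            class = c("homogeneous_network", "matrix", "array"))
}

#' @rdname homogeneous_network
#' @param entity_ids ordered identifiers of the entity columns.
#' @export
bipartite_network <- function(matrix, vocab, entity_ids, kind = "bipartite") {
  n <- length(vocab)
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop_input("entity identifiers must be unique")
  if (!is.matrix(matrix) || nrow(matrix) != n || ncol(matrix) != length(entity_ids))
    stop_input("matrix must be ", n, " x ", length(entity_ids))
  if (!all(matrix %in% c(0, 1))) stop_input("bipartite entries must be 0/1")
  dimnames(matrix) <- list(as.character(vocab), entity_ids)
  structure(matrix, vocab = vocab, kind = kind, entity_ids = entity_ids,
            class = c("bipartite_network", "matrix", "array"))
}

net_vocab <- function(net) attr(net, "vocab")
net_kind <- function(net) attr(net, "kind")

#' Build a drug-drug similarity network from per-drug data
#'
#' Applies a pairwise similarity measure to all drug pairs of a vocabulary.
#' Drugs with no data in the modality (`NULL` or empty entries of `data`) get
#' all-zero rows rather than being dropped, so one shared vocabulary works
#' across every network; such drugs are reported via a message.
#'
#' @param vocab a [drug_vocabulary()].
#' @param data named list (names = drug ids) of per-drug payloads, or a matrix
#'   whose rows are per-drug payloads (e.g. fingerprints).
#' @param measure a function of two payloads returning a similarity in
#'   \[0, 1\], or one of the built-in measure names `"tanimoto"`,
#'   `"set_tanimoto"`, `"jaccard"`, `"atc"`.
#' @param kind label stored on the result.
#' @param ... passed on to `measure`.
#' @return a [homogeneous_network()].
#' @examples
#' v <- drug_vocabulary(c("a", "b"))
#' fps <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' build_similarity_network(v, fps, "tanimoto")
#' @export
build_similarity_network <- function(vocab, data, measure, kind = NULL, ...) {
  if (is.character(measure)) {
    kind <- kind %||% measure
    measure <- switch(measure,
      tanimoto = tanimoto,
      set_tanimoto = set_tanimoto,
      jaccard = jaccard,
      atc = atc_similarity,
      stop_input("unknown measure: ", measure)
    )
  }
  kind <- kind %||% "similarity"
  n <- length(vocab)
  get <- if (is.matrix(data)) {
    function(i) data[i, ]
  } else {
    function(i) data[[as.character(vocab)[i]]]
  }
  has_data <- vapply(seq_len(n), function(i) {
    d <- get(i)
    !is.null(d) && length(d) > 0L
  }, logical(1))
  if (any(!has_data)) {
    message("no data for ", sum(!has_data), " drug(s) in '", kind,
            "' network; rows set to 0: ",
            paste(utils::head(as.character(vocab)[!has_data], 5), collapse = ", "))
  }
  S <- matrix(0, n, n)
  idx <- which(has_data)
  for (a in seq_along(idx)) {
    i <- idx[a]
    di <- get(i)
    S[i, i] <- measure(di, di, ...)
    for (b in seq_len(a - 1L)) {
      j <- idx[b]
      S[i, j] <- S[j, i] <- measure(di, get(j), ...)
    }
  }
  homogeneous_network(S, vocab, kind = kind)
}
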