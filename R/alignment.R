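#' Normalised Smith-Waterman sequence similarity
#'
#' Local-alignment similarity between two protein sequences. The raw
#' Smith-Waterman score `SW(a, b)` (affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`) is normalised to
#' `SW(a, b) / sqrt(SW(a, a) * SW(b, b))` so that self-similarity is 1 and
#' scores are comparable across sequence lengths. Sequences with no
#' positive-scoring local alignment score 0.
#'
#' @param seq_a,seq_b protein sequences (character strings over the
#'   20-letter amino-acid alphabet).
#' @param substitution substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 1).
#' @return similarity in \[0, 1\].
#' @examples
#' sw_similarity("HEAGAWGHEE", "HEAGAWGHEE") # 1
#' sw_similarity("AAAA", "CCCC")             # 0
#' @export
sw_similarity <- function(seq_a, seq_b, substitution = "BLOSUM62",
                          gap_open = 10, gap_extend = 1) {
  check_protein(seq_a)
  check_protein(seq_b)
  sub <- resolve_submat(substitution)
  saa <- sw_raw(seq_a, seq_a, sub, gap_open, gap_extend)
  sbb <- sw_raw(seq_b, seq_b, sub, gap_open, gap_extend)
  if (saa <= 0 || sbb <= 0) return(0) # degenerate self-score
  sab <- sw_raw(seq_a, seq_b, sub, gap_open, gap_extend)
  max(sab, 0) / sqrt(saa * sbb)
}

check_protein <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) < 1L)
    stop_input("sequences must be non-empty character scalars")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", toupper(s)))
    stop_input("invalid residue in sequence: ", s)
}

resolve_submat <- function(substitution) {
  if (is.matrix(substitution)) return(substitution)
  e <- new.env()
  utils::data(list = substitution, package = "Biostrings", envir = e)
  get(substitution, envir = e)
}

sw_raw <- function(a, b, sub, gap_open, gap_extend) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE
  )
  max(pa, 0)
}

#' Target-sequence similarity of two drugs
#'
#' Drug-level protein-target similarity: the mean of [sw_similarity()] over
#' the full Cartesian product of the two drugs' target sequences. Pairwise
#' sequence similarities can be precomputed once for a sequence library with
#' [sequence_similarity_matrix()] and reused across all drug pairs.
#'
#' @param targets_a,targets_b character vectors of protein sequences, or
#'   (when `seq_sim` is given) identifiers into its dimnames.
#' @param seq_sim optional precomputed sequence-by-sequence similarity matrix.
#' @param ... passed to [sw_similarity()].
#' @return similarity in \[0, 1\], or `NA` when either target set is empty
#'   (missing-data signal; network assembly maps it to 0).
#' @export
target_similarity <- function(targets_a, targets_b, seq_sim = NULL, ...) {
  if (length(targets_a) == 0L || length(targets_b) == 0L) return(NA_real_)
  if (!is.null(seq_sim)) {
    return(mean(seq_sim[as.character(targets_a), as.character(targets_b)]))
  }
  vals <- outer(targets_a, targets_b,
                Vectorize(function(x, y) sw_similarity(x, y, ...)))
  mean(vals)
}

#' @rdname target_similarity
#' @param seqs named character vector of unique protein sequences.
#' @return `sequence_similarity_matrix`: symmetric matrix of normalised
#'   Smith-Waterman similarities with unit diagonal.
#' @export
sequence_similarity_matrix <- function(seqs, substitution = "BLOSUM62",
                                       gap_open = 10, gap_extend = 1) {
  stopifnot(!is.null(names(seqs)))
  n <- length(seqs)
  sub <- resolve_submat(substitution)
  for (s in seqs) check_protein(s)
  aa <- Biostrings::AAStringSet(toupper(seqs))
  self <- vapply(seq_len(n), function(i) {
    sw_raw(seqs[i], seqs[i], sub, gap_open, gap_extend)
  }, numeric(1))
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    sc <- Biostrings::pairwiseAlignment(
      aa[(i + 1L):n], aa[[i]], type = "local", substitutionMatrix = sub,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    sc <- pmax(sc, 0) / sqrt(self[i] * self[(i + 1L):n])
    S[i, (i + 1L):n] <- S[(i + 1L):n, i] <- sc
  }
  dimnames(S) <- list(names(seqs), names(seqs))
  S
}
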