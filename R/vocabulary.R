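#' Drug vocabulary
#'
#' An ordered set of unique drug identifiers. The vocabulary fixes the row and
#' column order of every matrix in the pipeline: all nine input networks, the
#' PPMI matrices, the fused feature matrix and the association matrix index
#' drugs by their position here.
#'
#' @param ids character vector of drug identifiers.
#' @return An object of class `drug_vocabulary`: the identifier vector with an
#'   `index` attribute mapping identifier to 1-based position.
#' @examples
#' v <- drug_vocabulary(c("D1", "D2", "D3"))
#' vocab_index(v, c("D3", "D1"))
#' @export
drug_vocabulary <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_input("drug identifiers must be unique")
  if (length(ids) == 0L) stop_input("vocabulary must contain at least one drug")
  structure(ids, index = stats::setNames(seq_along(ids), ids),
            class = "drug_vocabulary")
}

#' @rdname drug_vocabulary
#' @param vocab a `drug_vocabulary`.
#' @param drugs identifiers to look up.
#' @export
vocab_index <- function(vocab, drugs) {
  idx <- attr(vocab, "index")[as.character(drugs)]
  if (anyNA(idx)) {
    stop_input("unknown drug identifier(s): ",
               paste(setdiff(drugs, names(attr(vocab, "index"))), collapse = ", "))
  }
  unname(idx)
}

#' @export
print.drug_vocabulary <- function(x, ...) {
  cat("Drug vocabulary:", length(x), "drugs\n")
  utils::head(unclass(x)) |> print()
  invisible(x)
}
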