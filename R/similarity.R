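#' Tanimoto coefficient on binary fingerprints
#'
#' Chemical-structure similarity of two drugs from fixed-length binary
#' fingerprints (MACCS-style 166-bit keys by default throughout the package).
#' With `a` and `b` the set-bit counts of the two fingerprints and `c` the
#' count of shared set bits, the coefficient is `c / (a + b - c)`, ranging
#' from 0 (no shared substructure keys) to 1. Two all-zero fingerprints give
#' 0 by convention: a pair with no evidence is treated as dissimilar rather
#' than undefined.
#'
#' @param fp_a,fp_b binary vectors (0/1) of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0, 1), c(1, 0, 1, 1)) # c=2, a=3, b=3 -> 0.5
#' @seealso [set_tanimoto()] for the same coefficient on annotation sets,
#'   [jaccard()] to which it is algebraically identical on bit supports.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop_input("fingerprints must have equal length (",
               length(fp_a), " vs ", length(fp_b), ")")
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1)))
    stop_input("fingerprint entries must be 0/1")
  a <- sum(fp_a)
  b <- sum(fp_b)
  cc <- sum(fp_a * fp_b)
  if (a + b == 0) return(0)
  cc / (a + b - cc)
}

#' Tanimoto coefficient on annotation sets
#'
#' The same `c / (a + b - c)` coefficient applied to two sets of annotations
#' (e.g. the side-effect profiles of two drugs): `a`, `b` are the set sizes
#' and `c` the intersection size. Two empty sets give 0 by convention.
#'
#' @param set_a,set_b vectors of annotation identifiers (duplicates ignored).
#' @return similarity in \[0, 1\].
#' @export
set_tanimoto <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  a <- length(set_a)
  b <- length(set_b)
  cc <- length(intersect(set_a, set_b))
  if (a + b == 0) return(0)
  cc / (a + b - cc)
}

#' Jaccard coefficient
#'
#' `|A ∩ B| / |A ∪ B|`; 0 when both sets are empty. On sets this equals
#' [set_tanimoto()]; it is kept as its own verb because the bipartite
#' networks are Jaccard-transformed before embedding.
#'
#' @param set_a,set_b vectors of identifiers (duplicates ignored).
#' @return coefficient in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Jaccard transform of a bipartite network
#'
#' Turns a drugs x entities incidence matrix into a drug-drug network whose
#' (i, j) entry is the Jaccard coefficient of the two drugs' entity sets.
#' Drugs with an empty row have zero similarity to everything, including
#' themselves (the empty-set convention), so the diagonal is 1 only for drugs
#' with at least one entity.
#'
#' @param bn a [bipartite_network()].
#' @return a [homogeneous_network()].
#' @export
jaccard_network <- function(bn) {
  if (!inherits(bn, "bipartite_network")) stop_input("expected a bipartite_network")
  M <- unclass(bn)
  attributes(M) <- list(dim = dim(bn))
  inter <- M %*% t(M)
  sizes <- rowSums(M)
  un <- outer(sizes, sizes, "+") - inter
  S <- ifelse(un > 0, inter / un, 0)
  homogeneous_network(S, net_vocab(bn), kind = paste0("jaccard_", net_kind(bn)))
}

#' Therapeutic-class similarity from ATC codes
#'
#' The Anatomical Therapeutic Chemical classification assigns each drug one
#' or more 7-character codes with five hierarchical levels (anatomical group,
#' therapeutic subgroup, pharmacological subgroup, chemical subgroup,
#' substance: `L` `01` `X` `E` `07`). A code pair scores the number of leading
#' levels on which it agrees, divided by 5; the drug-level similarity combines
#' all code pairs of the two drugs by their mean (default) or maximum.
#'
#' @param codes_a,codes_b character vectors of 5-level ATC codes.
#' @param combine `"mean"` (default) or `"max"` over code pairs.
#' @return similarity in \[0, 1\].
#' @examples
#' atc_similarity("N05AH04", "N06AB03") # share only level 1 -> 0.2
#' @export
atc_similarity <- function(codes_a, codes_b, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  codes_a <- unique(toupper(codes_a))
  codes_b <- unique(toupper(codes_b))
  ok <- grepl("^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$", c(codes_a, codes_b))
  if (!all(ok))
    stop_input("malformed ATC code(s): ",
               paste(c(codes_a, codes_b)[!ok], collapse = ", "))
  pair_score <- function(x, y) {
    lv <- c(1, 3, 4, 5, 7) # last character position of each level
    shared <- 0L
    for (p in lv) {
      if (substr(x, 1, p) == substr(y, 1, p)) shared <- shared + 1L else break
    }
    shared / 5
  }
  scores <- outer(codes_a, codes_b, Vectorize(pair_score))
  if (combine == "mean") mean(scores) else max(scores)
}
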