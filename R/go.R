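#' Gene Ontology DAG
#'
#' A rooted acyclic child-to-parent edge set over GO terms, each edge carrying
#' the semantic-contribution weight of its relation (`is_a` 0.8, `part_of`
#' 0.6 by default, following Wang's measure).
#'
#' @param edges data.frame with columns `child`, `parent` and either a
#'   numeric `weight` or a character `relation` column.
#' @param relation_weights named numeric vector mapping relation labels to
#'   weights in (0, 1).
#' @return object of class `go_dag`: list with `parents` (named list of
#'   parent vectors), `weights` (parallel edge weights) and `terms`.
#' @export
go_dag <- function(edges, relation_weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  if ("weight" %in% names(edges)) {
    w <- as.numeric(edges$weight)
  } else if ("relation" %in% names(edges)) {
    w <- relation_weights[as.character(edges$relation)]
    if (anyNA(w))
      stop_input("unknown relation(s): ",
                 paste(unique(edges$relation[is.na(w)]), collapse = ", "))
  } else stop_input("edges need a 'weight' or 'relation' column")
  if (any(w <= 0 | w >= 1)) stop_input("relation weights must lie in (0, 1)")
  terms <- unique(c(child, parent))
  parents <- split(parent, factor(child, levels = terms))
  weights <- split(unname(w), factor(child, levels = terms))
  dag <- structure(list(parents = parents, weights = weights, terms = terms),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  state <- stats::setNames(integer(length(dag$terms)), dag$terms) # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 1L) stop_input("GO DAG contains a cycle at term ", t)
    if (state[[t]] == 2L) return(invisible())
    state[[t]] <<- 1L
    for (p in dag$parents[[t]]) visit(p)
    state[[t]] <<- 2L
  }
  for (t in dag$terms) visit(t)
  invisible(dag)
}

## S-values of Wang's measure for one term: the term itself contributes 1 and
## each ancestor the maximum over DAG paths of the product of edge weights.
wang_svalues <- function(term, dag) {
  sv <- c(1)
  names(sv) <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- character(0)
    for (t in frontier) {
      ps <- dag$parents[[t]]
      if (is.null(ps) || length(ps) == 0L) next
      ws <- dag$weights[[t]]
      for (k in seq_along(ps)) {
        cand <- ws[k] * sv[[t]]
        cur <- sv[ps[k]]
        if (is.na(cur) || cand > cur) {
          sv[ps[k]] <- cand
          nxt <- c(nxt, ps[k])
        }
      }
    }
    frontier <- unique(nxt)
  }
  sv
}

#' Wang semantic similarity of two GO terms
#'
#' Graph-based measure: each term's ancestor closure (term included) is
#' assigned S-values — 1 for the term itself, and for an ancestor the best
#' path product of relation weights. The similarity is the summed S-values
#' of the shared ancestors under both terms, divided by the two terms'
#' total semantic values.
#'
#' @param t1,t2 GO term identifiers present in `dag`.
#' @param dag a [go_dag()].
#' @return similarity in \[0, 1\]; 1 iff `t1 == t2`, 0 when the terms share
#'   no ancestor.
#' @export
go_term_similarity <- function(t1, t2, dag) {
  t1 <- as.character(t1); t2 <- as.character(t2)
  miss <- setdiff(c(t1, t2), dag$terms)
  if (length(miss)) stop_input("unknown GO term(s): ", paste(miss, collapse = ", "))
  s1 <- wang_svalues(t1, dag)
  s2 <- wang_svalues(t2, dag)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0L) return(0)
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

## Best-match average of a term-by-term similarity matrix (rows = terms of
## gene a, cols = terms of gene b).
bma <- function(S) {
  (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) / (nrow(S) + ncol(S))
}

#' Gene-level and drug-level GO functional similarity
#'
#' `gene_go_similarity` compares two genes by the best-match average of the
#' Wang term similarity over their annotation sets. `drug_go_similarity`
#' lifts this to drugs: the mean of the gene-gene similarity over all pairs
#' of the two drugs' target-coding genes. Unannotated genes are excluded
#' from the pairing; if nothing remains the result is `NA` (missing data).
#'
#' @param genes_a,genes_b character vectors of gene identifiers.
#' @param annotations named list: gene id -> character vector of GO terms.
#' @param dag a [go_dag()].
#' @param term_sim optional precomputed term-by-term similarity matrix with
#'   dimnames (avoids recomputing S-values across many gene pairs).
#' @return similarity in \[0, 1\] or `NA`.
#' @export
drug_go_similarity <- function(genes_a, genes_b, annotations, dag,
                               term_sim = NULL) {
  keep <- function(g) {
    g <- as.character(g)
    g[vapply(g, function(x) length(annotations[[x]] %||% character(0)) > 0,
             logical(1))]
  }
  genes_a <- keep(genes_a)
  genes_b <- keep(genes_b)
  if (length(genes_a) == 0L || length(genes_b) == 0L) return(NA_real_)
  vals <- outer(genes_a, genes_b, Vectorize(function(x, y) {
    gene_go_similarity(x, y, annotations, dag, term_sim)
  }))
  mean(vals)
}

#' @rdname drug_go_similarity
#' @param gene_a,gene_b single gene identifiers.
#' @export
gene_go_similarity <- function(gene_a, gene_b, annotations, dag,
                               term_sim = NULL) {
  ta <- unique(as.character(annotations[[as.character(gene_a)]]))
  tb <- unique(as.character(annotations[[as.character(gene_b)]]))
  if (length(ta) == 0L || length(tb) == 0L) return(NA_real_)
  if (is.null(term_sim)) {
    term_sim_sub <- outer(ta, tb, Vectorize(function(x, y)
      go_term_similarity(x, y, dag)))
  } else {
    term_sim_sub <- term_sim[ta, tb, drop = FALSE]
  }
  bma(term_sim_sub)
}

#' @rdname drug_go_similarity
#' @param terms terms to include (default all terms of the DAG).
#' @export
go_term_similarity_matrix <- function(dag, terms = dag$terms) {
  terms <- as.character(terms)
  sv <- lapply(terms, wang_svalues, dag = dag)
  names(sv) <- terms
  tot <- vapply(sv, sum, numeric(1))
  n <- length(terms)
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- intersect(names(sv[[i]]), names(sv[[j]]))
    S[i, j] <- S[j, i] <- if (length(common) == 0L) 0 else
      (sum(sv[[i]][common]) + sum(sv[[j]][common])) / (tot[i] + tot[j])
  }
  dimnames(S) <- list(terms, terms)
  S
}
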