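## 5-term toy DAG: root A; B, C children of A; D, E children of B
toy_dag_edges <- data.frame(
  child = c("B", "C", "D", "E"),
  parent = c("A", "A", "B", "B"),
  relation = c("is_a", "part_of", "is_a", "part_of")
)

test_that("Wang term similarity matches exhaustive S-value propagation", {
  dag <- go_dag(toy_dag_edges)
  parents <- list(B = "A", C = "A", D = "B", E = "B")
  weights <- list(B = 0.8, C = 0.6, D = 0.8, E = 0.6)
  terms <- c("A", "B", "C", "D", "E")
  for (t1 in terms) for (t2 in terms) {
    expect_equal(go_term_similarity(t1, t2, dag),
                 oracle_wang_sim(t1, t2, parents, weights),
                 label = paste(t1, t2))
  }
  expect_equal(go_term_similarity("D", "D", dag), 1)
  expect_error(go_term_similarity("D", "ZZ", dag), "unknown GO term")
})

test_that("Wang similarity handles multi-parent DAGs and random weights", {
  set.seed(8)
  for (rep in 1:5) {
    # random DAG on up to 10 terms: term i may attach to earlier terms
    n <- sample(5:10, 1)
    terms <- paste0("T", seq_len(n))
    parents <- list()
    weights <- list()
    edges <- NULL
    for (i in 2:n) {
      ps <- sample(terms[seq_len(i - 1L)], sample(1:min(2, i - 1L), 1))
      ws <- round(runif(length(ps), 0.3, 0.9), 3)
      parents[[terms[i]]] <- ps
      weights[[terms[i]]] <- ws
      edges <- rbind(edges, data.frame(child = terms[i], parent = ps,
                                       weight = ws))
    }
    dag <- go_dag(edges)
    for (k in 1:10) {
      pick <- sample(terms, 2)
      expect_equal(go_term_similarity(pick[1], pick[2], dag),
                   oracle_wang_sim(pick[1], pick[2], parents, weights),
                   tolerance = 1e-12)
    }
  }
})

test_that("terms in disjoint DAG components have zero similarity", {
  dag <- go_dag(data.frame(child = c("B", "D"), parent = c("A", "C"),
                           relation = "is_a"))
  expect_equal(go_term_similarity("B", "D", dag), 0)
})

test_that("a cyclic edge table is rejected", {
  expect_error(go_dag(data.frame(child = c("A", "B"), parent = c("B", "A"),
                                 relation = "is_a")),
               "cycle")
})

test_that("drug-level GO similarity is the mean of best-match-average gene pairs", {
  dag <- go_dag(toy_dag_edges)
  ann <- list(g1 = c("D", "E"), g2 = c("C"), g3 = c("D"), g4 = c("B", "C"))
  # gene-gene BMA oracle by enumeration
  bma_oracle <- function(ta, tb) {
    S <- outer(ta, tb, Vectorize(function(x, y) go_term_similarity(x, y, dag)))
    (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (length(ta) + length(tb))
  }
  expect_equal(gene_go_similarity("g1", "g4", ann, dag),
               bma_oracle(ann$g1, ann$g4))
  # 2x2 gene toy: mean of the four BMA values
  manual <- mean(c(bma_oracle(ann$g1, ann$g3), bma_oracle(ann$g1, ann$g4),
                   bma_oracle(ann$g2, ann$g3), bma_oracle(ann$g2, ann$g4)))
  expect_equal(drug_go_similarity(c("g1", "g2"), c("g3", "g4"), ann, dag),
               manual)
  # identical singleton gene sets
  expect_equal(drug_go_similarity("g1", "g1", ann, dag), 1)
  # unannotated genes are excluded; nothing left -> NA
  expect_true(is.na(drug_go_similarity("g9", c("g3"), ann, dag)))
})

test_that("the vectorised gene similarity matrix matches pairwise calls", {
  dag <- go_dag(toy_dag_edges)
  ann <- list(g1 = c("D", "E"), g2 = c("C"), g3 = c("D"), g4 = c("B", "C"))
  G <- gene_similarity_matrix(names(ann), ann, dag)
  for (a in names(ann)) for (b in names(ann)) {
    if (a == b) next
    expect_equal(G[a, b], gene_go_similarity(a, b, ann, dag),
                 label = paste(a, b))
  }
})
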