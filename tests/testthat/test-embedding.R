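test_that("transition matrix row-normalises and repairs zero rows", {
  expect_equal(transition_matrix(diag(3)), diag(3))
  expect_equal(transition_matrix(matrix(c(0, 2, 2, 0), 2)),
               matrix(c(0, 1, 1, 0), 2))
  M <- transition_matrix(rbind(c(0, 0, 0), c(1, 0, 1), c(0, 4, 0)))
  expect_equal(M[1, ], rep(1 / 3, 3)) # isolated node -> uniform
  expect_equal(rowSums(M), rep(1, 3))
  expect_error(transition_matrix(matrix(c(1, -1, 0, 1), 2)), "non-negative")
})

test_that("random-walk co-occurrence follows the restart recurrence", {
  # omega = 0: every step returns the restart distribution, C = k * I
  M <- transition_matrix(matrix(runif(16) + 0.1, 4))
  C <- rwr_cooccurrence(M, omega = 0, walk_length = 5)
  expect_equal(C, 5 * diag(4))
  # omega = 1 on the 2-cycle, k = 2: p1 + p2 = (0,1) + (1,0)
  M2 <- matrix(c(0, 1, 1, 0), 2)
  C2 <- rwr_cooccurrence(M2, omega = 1, walk_length = 2)
  expect_equal(C2, matrix(1, 2, 2))
  # hand iteration oracle on a random chain
  set.seed(9)
  A <- matrix(runif(25), 5)
  M5 <- transition_matrix(A)
  omega <- 0.4; k <- 4
  C5 <- rwr_cooccurrence(M5, omega, k)
  for (i in 1:5) {
    p0 <- replace(numeric(5), i, 1)
    p <- p0
    acc <- numeric(5)
    for (s in 1:k) {
      p <- omega * (p %*% M5)[1, ] + (1 - omega) * p0
      acc <- acc + p
    }
    expect_equal(unname(C5[i, ]), acc)
  }
})

test_that("co-occurrence conserves probability mass (row sums = k)", {
  set.seed(2)
  for (rep in 1:5) {
    M <- transition_matrix(matrix(runif(36) * rbinom(36, 1, 0.5), 6))
    k <- sample(1:6, 1)
    C <- rwr_cooccurrence(M, runif(1), k)
    expect_equal(rowSums(C), rep(k, 6), tolerance = 1e-6)
    expect_true(all(C >= 0))
  }
})

test_that("long walks approach the stationary mixture of the restart chain", {
  set.seed(13)
  A <- matrix(runif(36) + 0.05, 6)
  A <- (A + t(A)) / 2
  M <- transition_matrix(A)
  omega <- 0.5
  C <- rwr_cooccurrence(M, omega, 100)
  # power-iteration oracle: stationary distribution of the restart chain
  # from start i solves pi = omega * pi M + (1 - omega) e_i
  for (i in c(1, 4)) {
    p0 <- replace(numeric(6), i, 1)
    pi_s <- p0
    for (s in 1:500) pi_s <- omega * (pi_s %*% M)[1, ] + (1 - omega) * p0
    expect_equal(unname(C[i, ]) / 100, pi_s, tolerance = 0.02)
  }
})

test_that("PPMI matches the definition and a brute-force oracle", {
  P <- ppmi(matrix(c(2, 0, 0, 2), 2))
  expect_equal(unclass(P)[], matrix(c(log(2), 0, 0, log(2)), 2),
               ignore_attr = TRUE)
  # constant matrix -> all zeros
  expect_equal(max(abs(ppmi(matrix(3, 4, 4)))), 0)
  set.seed(4)
  for (rep in 1:10) {
    C <- matrix(rpois(25, 2), 5)
    if (sum(C) == 0) C[1, 1] <- 1
    expect_equal(unclass(ppmi(C))[], oracle_ppmi(C), ignore_attr = TRUE)
  }
  expect_error(ppmi(matrix(0, 2, 2)), "no mass")
})

test_that("PPMI is invariant to global scaling of the co-occurrence matrix", {
  set.seed(6)
  C <- matrix(rpois(36, 3), 6)
  expect_equal(unclass(ppmi(C))[], unclass(ppmi(2 * C))[])
  expect_equal(unclass(ppmi(C))[], unclass(ppmi(0.1 * C))[])
})

test_that("embed_all routes homogeneous and bipartite networks correctly", {
  v <- drug_vocabulary(paste0("d", 1:4))
  set.seed(3)
  A <- matrix(runif(16), 4)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  hn <- homogeneous_network(A, v, kind = "sim")
  inc <- matrix(rbinom(12, 1, 0.5), 4)
  bn <- bipartite_network(inc, v, paste0("e", 1:3), kind = "bip")
  out <- embed_all(list(hn, bn), omega = 0.5, walk_length = 3)
  expect_length(out, 2)
  # homogeneous route: transition -> walk -> self-mass removal -> ppmi
  Ch <- rwr_cooccurrence(transition_matrix(hn), 0.5, 3)
  diag(Ch) <- 0
  expect_equal(unclass(out[[1]])[], unclass(ppmi(Ch))[], ignore_attr = TRUE)
  # bipartite route: jaccard -> transition -> walk -> self-mass removal -> ppmi
  Cb <- rwr_cooccurrence(transition_matrix(jaccard_network(bn)), 0.5, 3)
  diag(Cb) <- 0
  expect_equal(unclass(out[[2]])[], unclass(ppmi(Cb))[], ignore_attr = TRUE)
  # drop_self = FALSE keeps the raw pipeline composition
  out_raw <- embed_all(list(hn, bn), drop_self = FALSE)
  manual_h <- ppmi(rwr_cooccurrence(transition_matrix(hn), 0.5, 3))
  expect_equal(unclass(out_raw[[1]])[], unclass(manual_h)[], ignore_attr = TRUE)
  # rwr_bipartite = FALSE takes PPMI of the Jaccard matrix directly
  out2 <- embed_all(list(hn, bn), rwr_bipartite = FALSE, drop_self = FALSE)
  expect_equal(unclass(out2[[2]])[],
               unclass(ppmi(as.matrix(jaccard_network(bn))))[],
               ignore_attr = TRUE)
  # identical networks give identical PPMI matrices
  out3 <- embed_all(list(hn, hn, hn))
  expect_equal(out3[[1]], out3[[3]])
  # mismatched vocabularies are rejected
  v2 <- drug_vocabulary(paste0("x", 1:4))
  hn2 <- homogeneous_network(A, v2)
  expect_error(embed_all(list(hn, hn2)), "vocabulary")
})
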