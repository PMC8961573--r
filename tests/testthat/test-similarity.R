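test_that("Tanimoto coefficient matches its closed form and conventions", {
  # identical non-zero fingerprints
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  # disjoint
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # a = 10, b = 8, c = 4 -> 4/14
  fa <- c(rep(1, 10), rep(0, 8))
  fb <- c(rep(0, 6), rep(1, 8), rep(0, 4))
  expect_equal(sum(fa), 10)
  expect_equal(sum(fb), 8)
  expect_equal(sum(fa * fb), 4)
  expect_equal(tanimoto(fa, fb), 4 / 14)
  # both empty -> 0 by convention
  expect_equal(tanimoto(numeric(5), numeric(5)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("set Tanimoto and Jaccard agree with set arithmetic", {
  expect_equal(set_tanimoto(c("s1", "s2", "s3"), c("s3", "s4")), 1 / 4)
  expect_equal(set_tanimoto(character(0), character(0)), 0)
  expect_equal(set_tanimoto(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 5)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("tanimoto equals jaccard on the supports of fingerprints", {
  set.seed(11)
  for (k in 1:20) {
    fa <- rbinom(40, 1, 0.4)
    fb <- rbinom(40, 1, 0.4)
    expect_equal(tanimoto(fa, fb),
                 jaccard(which(fa == 1), which(fb == 1)))
  }
})

test_that("shared items increase and unshared items decrease both coefficients", {
  set.seed(5)
  for (k in 1:10) {
    a <- sample(letters, 8)
    b <- sample(letters, 8)
    base_t <- set_tanimoto(a, b)
    shared <- "ZZ"
    expect_gte(set_tanimoto(c(a, shared), c(b, shared)), base_t)
    expect_lte(set_tanimoto(c(a, "YY"), b), base_t)
    expect_gte(jaccard(c(a, shared), c(b, shared)), jaccard(a, b))
    expect_lte(jaccard(c(a, "YY"), b), jaccard(a, b))
  }
})

test_that("jaccard_network matches exhaustive pairwise computation", {
  v <- drug_vocabulary(c("d1", "d2", "d3"))
  inc <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 0, 0))
  bn <- bipartite_network(inc, v, paste0("e", 1:4))
  net <- jaccard_network(bn)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(net[i, j], jaccard(which(inc[i, ] == 1), which(inc[j, ] == 1)))
  }
  # empty row scores 0 even against itself
  expect_equal(net[3, 3], 0)
  # one drug with items
  bn1 <- bipartite_network(matrix(c(1, 1, 0), 1), drug_vocabulary("x"),
                           paste0("e", 1:3))
  expect_equal(as.numeric(jaccard_network(bn1)), 1)
})

test_that("ATC similarity counts leading matched levels out of five", {
  expect_equal(atc_similarity("N05AH04", "N05AH04"), 1)
  expect_equal(atc_similarity("N05AH04", "N06AB03"), 0.2) # level 1 only
  expect_equal(atc_similarity("N05AH04", "A06AB03"), 0)
  expect_equal(atc_similarity("N05AH04", "N05AH03"), 0.8)
  # multiple codes: mean over code pairs, or max when requested
  expect_equal(atc_similarity(c("N05AH04", "A01AB01"), "N05AH04"),
               mean(c(1, 0)))
  expect_equal(atc_similarity(c("N05AH04", "A01AB01"), "N05AH04",
                              combine = "max"), 1)
  expect_error(atc_similarity("XYZ", "N05AH04"), "malformed")
})

test_that("build_similarity_network applies measures symmetrically", {
  v <- drug_vocabulary(c("a", "b", "c", "d", "e"))
  set.seed(20)
  fps <- matrix(rbinom(5 * 20, 1, 0.4), 5, dimnames = list(as.character(v), NULL))
  net <- build_similarity_network(v, fps, "tanimoto")
  expect_s3_class(net, "homogeneous_network")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(net[i, j], tanimoto(fps[i, ], fps[j, ]))
  }
  expect_true(all(net >= 0 & net <= 1))
  expect_lt(max(abs(net - t(net))), 1e-9)
  # single drug
  n1 <- build_similarity_network(drug_vocabulary("z"),
                                 matrix(c(1, 0, 1), 1), "tanimoto")
  expect_equal(as.numeric(n1), 1)
  # permuting the vocabulary permutes rows and columns consistently
  perm <- c(3, 1, 5, 2, 4)
  v2 <- drug_vocabulary(as.character(v)[perm])
  net2 <- build_similarity_network(v2, fps[perm, , drop = FALSE], "tanimoto")
  expect_equal(unclass(net2)[as.character(v), as.character(v)],
               unclass(net)[as.character(v), as.character(v)])
  expect_error(build_similarity_network(v, fps, "nope"), "unknown measure")
})

test_that("drugs lacking modality data get zero rows, not dropped", {
  v <- drug_vocabulary(c("a", "b", "c"))
  dat <- list(a = c("s1", "s2"), b = character(0), c = c("s2", "s3"))
  expect_message(net <- build_similarity_network(v, dat, "set_tanimoto"),
                 "no data")
  expect_equal(unname(net["b", ]), c(0, 0, 0))
  expect_equal(net["a", "c"], set_tanimoto(dat$a, dat$c))
})
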