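## small shared fixture: 3 networks over 12 drugs with two blocks
make_mats <- function(n = 12, G = 3, seed = 5) {
  set.seed(seed)
  lapply(seq_len(G), function(g) {
    base <- matrix(runif(n * n, 0, 0.2), n)
    base[1:(n / 2), 1:(n / 2)] <- base[1:(n / 2), 1:(n / 2)] + 0.6
    base[(n / 2 + 1):n, (n / 2 + 1):n] <- base[(n / 2 + 1):n, (n / 2 + 1):n] + 0.6
    pmin(base, 1)
  })
}

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(per_network_hidden = 8L, joint_hidden = 10L, embedding_dim = 4L,
         epochs = 80L, dropout_rate = 0),
    list(...))
  do.call(mae_config, args)
}

test_that("min-max scaling maps each network onto the unit interval", {
  M1 <- matrix(c(0, 0.25, 0.5, 1), 2) # already spans [0, 1]
  M2 <- matrix(c(2, 4, 6, 10), 2)
  out <- scale_inputs(list(M1, M2))
  expect_equal(out[[1]], M1)
  expect_equal(min(out[[2]]), 0)
  expect_equal(max(out[[2]]), 1)
  expect_equal(out[[2]], (M2 - 2) / 8)
  expect_warning(res <- scale_inputs(list(matrix(3, 2, 2))), "constant")
  expect_equal(res[[1]], matrix(0, 2, 2))
  # scaling parameters recorded for reproducibility
  sc <- attr(scale_inputs(list(M2)), "scaling")
  expect_equal(unname(sc[[1]]), c(2, 8))
})

test_that("the autoencoder has the promised architecture and parameter count", {
  cfg <- small_cfg()
  m <- build_mae(cfg, n_networks = 3, n_drugs = 12)
  n <- 12; G <- 3; h1 <- 8; h2 <- 10; d <- 4
  expected <- G * (n * h1 + h1) +          # per-network encoders
    (G * h1 * h2 + h2) +                   # joint layer
    (h2 * d + d) +                         # embedding layer
    (d * h2 + h2) +                        # decoder mirror of embedding
    (h2 * G * h1 + G * h1) +               # decoder mirror of joint
    G * (h1 * n + n)                       # reconstruction heads
  expect_equal(sum(lengths(m$params)), expected)
  # same seed -> identical initialisation; different seed -> different
  m2 <- build_mae(cfg, 3, 12)
  expect_identical(m$params, m2$params)
  cfg3 <- small_cfg(seed = 99L)
  expect_false(identical(build_mae(cfg3, 3, 12)$params, m$params))
  # encoder output dimension is the embedding width
  F <- extract_features(m, make_mats())
  expect_equal(dim(F), c(12L, 4L))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(3)
  G <- 3; n <- 7; B <- 5
  mats <- replicate(G, matrix(runif(B * n), B, n), simplify = FALSE)
  cfg <- mae_config(per_network_hidden = 4, joint_hidden = 5,
                    embedding_dim = 3, dropout_rate = 0, seed = 2)
  m <- build_mae(cfg, G, n)
  fw <- otrepo:::mae_forward(m$params, mats, G)
  grads <- otrepo:::mae_backward(m$params, fw, mats, G)
  lossfn <- function(params) {
    otrepo:::mae_batch_loss(otrepo:::mae_forward(params, mats, G), mats, G)$total
  }
  for (nm in names(m$params)) {
    p <- m$params
    i <- sample(length(p[[nm]]), 1)
    h <- 1e-6
    p[[nm]][i] <- p[[nm]][i] + h; up <- lossfn(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * h; dn <- lossfn(p)
    expect_equal(grads[[nm]][i], (up - dn) / (2 * h), tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("training reduces the reconstruction loss and is reproducible", {
  mats <- make_mats()
  m0 <- build_mae(small_cfg(seed = 7L), 3, 12)
  m <- train_mae(m0, mats)
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
  expect_true(all(is.finite(m$history$loss)))
  # same seed reproduces the trajectory
  m2 <- train_mae(build_mae(small_cfg(seed = 7L), 3, 12), mats)
  expect_equal(m$history$loss, m2$history$loss, tolerance = 1e-10)
  # zero epochs returns the initialised model unchanged
  m00 <- train_mae(build_mae(small_cfg(epochs = 0L), 3, 12), mats)
  expect_identical(m00$params, build_mae(small_cfg(epochs = 0L), 3, 12)$params)
  expect_false(m00$trained)
  # training must not mutate the untrained model (in-place optimiser safety)
  expect_identical(m0$params, build_mae(small_cfg(seed = 7L), 3, 12)$params)
})

test_that("identical inputs across networks give near-identical branch losses", {
  set.seed(8)
  M <- make_mats(G = 1)[[1]]
  mats <- list(M, M, M)
  m <- train_mae(build_mae(small_cfg(epochs = 40L), 3, 12), mats)
  per <- m$history_per_network[nrow(m$history_per_network), ]
  expect_lt(diff(range(per)), 0.15 * mean(per))
})

test_that("feature extraction is deterministic and respects input identity", {
  mats <- make_mats()
  m <- train_mae(build_mae(small_cfg(), 3, 12), mats)
  F1 <- extract_features(m, mats)
  F2 <- extract_features(m, mats)
  expect_identical(F1, F2)
  # drugs with identical rows across all networks get identical features
  mats_dup <- lapply(mats, function(M) { M[2, ] <- M[1, ]; M })
  Fd <- extract_features(m, mats_dup)
  expect_equal(Fd[1, ], Fd[2, ])
})

test_that("training separates planted blocks in feature space", {
  mats <- make_mats(n = 12, G = 3, seed = 10)
  m <- train_mae(build_mae(small_cfg(epochs = 200L, seed = 7L), 3, 12), mats)
  F <- extract_features(m, mats)
  Fn <- F / sqrt(rowSums(F^2))
  CS <- Fn %*% t(Fn)
  block <- rep(1:2, each = 6)
  same <- outer(block, block, "==") & upper.tri(CS)
  other <- !outer(block, block, "==") & upper.tri(CS)
  expect_gt(mean(CS[same]), mean(CS[other]))
})

test_that("held-out reconstruction improves over the untrained model", {
  mats <- make_mats(n = 20, seed = 12)
  hold <- 19:20
  train_rows <- lapply(mats, function(M) M[1:18, , drop = FALSE])
  m0 <- build_mae(small_cfg(epochs = 150L), 3, 20)
  m <- train_mae(m0, train_rows)
  l_trained <- mae_loss(m, mats, rows = hold)
  l_untrained <- mae_loss(m0, mats, rows = hold)
  expect_true(is.finite(l_trained))
  expect_lt(l_trained, l_untrained)
})
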