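## tiny association problem with two drug blocks and aligned diseases
make_assoc <- function(n_drugs = 16, n_dis = 6, seed = 4) {
  set.seed(seed)
  F <- matrix(runif(n_drugs * 5, 0, 0.2), n_drugs)
  F[1:(n_drugs / 2), 1:2] <- F[1:(n_drugs / 2), 1:2] + 0.7
  F[(n_drugs / 2 + 1):n_drugs, 3:4] <- F[(n_drugs / 2 + 1):n_drugs, 3:4] + 0.7
  rownames(F) <- paste0("d", seq_len(n_drugs))
  block <- rep(1:2, each = n_drugs / 2)
  X <- matrix(0, n_dis, n_drugs,
              dimnames = list(paste0("x", seq_len(n_dis)), rownames(F)))
  dis_block <- rep(1:2, length.out = n_dis)
  for (i in seq_len(n_dis)) {
    members <- which(block == dis_block[i])
    X[i, sample(members, length(members) - 2)] <- 1
  }
  list(F = F, X = X, block = block, dis_block = dis_block)
}

tiny_wvae_cfg <- function(...) {
  wvae_config(latent_dim = 4L, hidden = 16L, input_dense = 8L,
              dropout_rate = 0, ...)
}

test_that("the model builds with seeded initialisation and checks shapes", {
  a <- make_assoc()
  m1 <- build_wvae(16, a$F, tiny_wvae_cfg(seed = 3L))
  m2 <- build_wvae(16, a$F, tiny_wvae_cfg(seed = 3L))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params,
                         build_wvae(16, a$F, tiny_wvae_cfg(seed = 4L))$params))
  expect_error(build_wvae(10, a$F, tiny_wvae_cfg()), "one row per drug")
})

test_that("encoder/decoder gradients match finite differences (diagonal mode)", {
  a <- make_assoc(n_drugs = 8, n_dis = 4)
  cfg <- tiny_wvae_cfg(seed = 11L)
  m <- build_wvae(8, a$F, cfg)
  X <- a$X[, 1:8, drop = FALSE]
  X <- (X + 0) # plain matrix
  F <- a$F[1:8, , drop = FALSE]
  Pn <- otrepo:::normalize_rows(X)
  set.seed(2)
  Eps <- matrix(rnorm(nrow(X) * cfg$latent_dim), nrow(X))
  alpha <- 0.2; aux_w <- 0.3
  lossfn <- function(params) {
    fw <- otrepo:::wvae_forward(params, X, F, Pn, deterministic = FALSE,
                                Eps = Eps)
    p <- pmin(pmax(fw$Xhat, 1e-7), 1 - 1e-7)
    aux <- -rowSums(X * log(p) + (1 - X) * log(1 - p))
    kl <- rowSums(-0.5 * (1 + 2 * fw$Ls - fw$Mu^2 - exp(2 * fw$Ls)))
    w <- rowMeans((X - fw$Xhat)^2)
    mean(w + alpha * kl + aux_w * aux)
  }
  fw <- otrepo:::wvae_forward(m$params, X, F, Pn, deterministic = FALSE,
                              Eps = Eps)
  dW_dXhat <- 2 * (fw$Xhat - X) / ncol(X)
  dS <- (aux_w * (fw$Xhat - X) + dW_dXhat * fw$Xhat * (1 - fw$Xhat)) / nrow(X)
  grads <- otrepo:::wvae_backward(m$params, fw, X, F, dS, Eps, NULL,
                                  alpha = alpha, B = nrow(X))
  for (nm in names(m$params)) {
    p <- m$params
    i <- sample(length(p[[nm]]), 1)
    h <- 1e-6
    p[[nm]][i] <- p[[nm]][i] + h; up <- lossfn(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * h; dn <- lossfn(p)
    expect_equal(unname(grads[[nm]][i]), (up - dn) / (2 * h),
                 tolerance = 1e-4, label = paste("grad", nm))
  }
})

test_that("training reduces the composite loss in both transport modes", {
  a <- make_assoc()
  for (mode in c("diagonal", "sinkhorn")) {
    w <- loss_weights(ot_mode = mode)
    m <- train_wvae(build_wvae(16, a$F, tiny_wvae_cfg(epochs = 60L, seed = 7L)),
                    a$X, w)
    expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
    expect_true(all(is.finite(m$history$loss)))
    # KL and auxiliary components stay non-negative throughout
    expect_true(all(m$history$kl > -1e-9))
    expect_true(all(m$history$aux >= 0))
    expect_true(all(m$history$wasserstein >= -1e-12))
  }
})

test_that("same-seed training reproduces the final loss exactly", {
  a <- make_assoc()
  m1 <- train_wvae(build_wvae(16, a$F, tiny_wvae_cfg(epochs = 40L, seed = 5L)),
                   a$X, loss_weights())
  m2 <- train_wvae(build_wvae(16, a$F, tiny_wvae_cfg(epochs = 40L, seed = 5L)),
                   a$X, loss_weights())
  expect_equal(utils::tail(m1$history$loss, 1), utils::tail(m2$history$loss, 1),
               tolerance = 1e-12)
  expect_identical(m1$params, m2$params)
})

test_that("with zero associations and no KL the scores are driven toward zero", {
  a <- make_assoc(n_drugs = 10, n_dis = 3)
  X0 <- a$X[, 1:10, drop = FALSE] * 0
  F <- a$F[1:10, , drop = FALSE]
  w <- loss_weights(alpha = 0, aux_weight = 1, ot_mode = "diagonal")
  expect_warning(
    m <- train_wvae(build_wvae(10, F, tiny_wvae_cfg(epochs = 300L, seed = 2L)),
                    X0, w),
    "all-zero")
  Pn <- otrepo:::normalize_rows(X0)
  sc <- otrepo:::wvae_forward(m$params, X0, F, Pn)$Xhat
  expect_lt(max(sc), 0.15)
})

test_that("prediction is deterministic, ranked, and flags known positives", {
  a <- make_assoc()
  m <- train_wvae(build_wvae(16, a$F, tiny_wvae_cfg(epochs = 60L, seed = 7L)),
                  a$X, loss_weights(ot_mode = "diagonal"))
  t1 <- predict(m, a$X, mask_known = TRUE)
  t2 <- predict(m, a$X, mask_known = TRUE)
  expect_identical(t1, t2)
  expect_true(all(t1$score >= 0 & t1$score <= 1))
  for (d in rownames(a$X)) {
    sl <- t1[t1$disease_id == d, ]
    expect_equal(sl$rank, seq_len(16))
    expect_true(all(diff(sl$score) <= 0))
    expect_setequal(sl$drug_id[sl$known], colnames(a$X)[a$X[d, ] == 1])
  }
})

test_that("the trained model ranks held-out block members above other drugs", {
  a <- make_assoc(n_drugs = 20, n_dis = 8, seed = 9)
  # hide two positives of disease x1
  X <- a$X
  pos <- which(X["x1", ] == 1)
  hidden <- pos[1:2]
  X["x1", hidden] <- 0
  m <- train_wvae(build_wvae(20, a$F, tiny_wvae_cfg(epochs = 150L, seed = 7L)),
                  X, loss_weights())
  tab <- predict(m, X["x1", , drop = FALSE], mask_known = TRUE)
  novel <- tab[!tab$known, ]
  hidden_rank <- match(colnames(X)[hidden], novel$drug_id)
  decoy_rank <- match(setdiff(novel$drug_id,
                              colnames(X)[a$block == a$dis_block[1]]),
                      novel$drug_id)
  expect_lt(stats::median(hidden_rank), stats::median(decoy_rank))
})
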