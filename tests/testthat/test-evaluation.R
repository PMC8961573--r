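test_that("AUROC matches exhaustive pair counting, including ties", {
  # perfectly separated
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # all scores equal -> 0.5
  expect_equal(auroc(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 6-point toy with one tie
  sc <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  lb <- c(1, 1, 0, 0, 1, 0)
  expect_equal(auroc(sc, lb), oracle_auroc(sc, lb))
  # random instances up to 50 points
  set.seed(17)
  for (k in 1:20) {
    n <- sample(10:50, 1)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    sc <- sample(seq(0, 1, 0.05), n, TRUE) # coarse grid forces ties
    expect_equal(auroc(sc, lb), oracle_auroc(sc, lb))
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(18)
  sc <- runif(30)
  lb <- rbinom(30, 1, 0.5)
  if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
  a <- auroc(sc, lb)
  expect_equal(auroc(10 * sc - 3, lb), a)
  expect_equal(auroc(exp(sc), lb), a)
  expect_equal(auroc(rank(sc, ties.method = "average"), lb), a)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  sc <- runif(40)
  lb <- rbinom(40, 1, 0.5)
  if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
  expect_equal(auroc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("80:20 splits are disjoint, exhaustive and reproducible", {
  set.seed(30)
  drugs <- paste0("d", 1:40)
  positives <- data.frame(
    disease_id = rep(paste0("x", 1:5), each = 20),
    drug_id = sample(drugs, 100, TRUE)
  )
  positives <- unique(positives)
  plan <- split_pairs(positives, drugs, ratio = 0.8, seed = 99)
  expect_equal(nrow(plan$train) + nrow(plan$test), nrow(positives))
  k <- function(df) paste(df$disease_id, df$drug_id)
  expect_length(intersect(k(plan$train), k(plan$test)), 0)
  # roughly 80:20 overall (stratification rounds per disease)
  expect_equal(nrow(plan$test) / nrow(positives), 0.2, tolerance = 0.05)
  # negatives avoid every positive and match partition sizes 1:1
  expect_equal(nrow(plan$train_negatives), nrow(plan$train))
  expect_equal(nrow(plan$test_negatives), nrow(plan$test))
  expect_length(intersect(k(positives),
                          k(rbind(plan$train_negatives, plan$test_negatives))),
                0)
  # same seed reproduces the split exactly
  plan2 <- split_pairs(positives, drugs, ratio = 0.8, seed = 99)
  expect_identical(plan, plan2)
  expect_error(split_pairs(positives[1:3, ], drugs), "at least 5")
})

test_that("split and fold invariants hold across many random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n_dis <- sample(4:8, 1)
    n_drug <- sample(20:30, 1)
    drugs <- paste0("d", seq_len(n_drug))
    pos <- unique(data.frame(
      disease_id = sample(paste0("x", seq_len(n_dis)), 30, TRUE),
      drug_id = sample(drugs, 30, TRUE)
    ))
    plan <- split_pairs(pos, drugs, seed = rep)
    k <- function(df) paste(df$disease_id, df$drug_id)
    expect_length(intersect(k(plan$train), k(plan$test)), 0)
    expect_setequal(c(k(plan$train), k(plan$test)), k(pos))
  }
})

test_that("rank_report returns novel candidates in score order", {
  set.seed(40)
  F <- matrix(runif(20 * 4), 20)
  rownames(F) <- paste0("d", 1:20)
  X <- matrix(rbinom(3 * 20, 1, 0.3), 3, 20,
              dimnames = list(paste0("x", 1:3), rownames(F)))
  m <- train_wvae(build_wvae(20, F, wvae_config(latent_dim = 4, hidden = 16,
                                                input_dense = 8, epochs = 30,
                                                seed = 2)),
                  X, loss_weights(ot_mode = "diagonal"))
  rep5 <- rank_report(m, X, "x2", top_k = 5)
  expect_equal(nrow(rep5), 5)
  expect_false(any(rep5$known))
  expect_true(all(diff(rep5$score) <= 0))
  # top_k = all drugs returns every novel drug
  all_rep <- rank_report(m, X, "x2", top_k = 20)
  expect_equal(nrow(all_rep), sum(X["x2", ] == 0))
  expect_error(rank_report(m, X, "nope"), "unknown disease")
})
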