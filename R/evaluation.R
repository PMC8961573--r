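#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counted one half. Equivalent
#' to integrating the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop_input("scores/labels length mismatch")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop_input("both classes must be present")
  r <- rank(scores) # midranks handle ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

## pair universe helpers -------------------------------------------------

pair_key <- function(disease, drug) paste(disease, drug, sep = "\r")

## sample `n` negative (unobserved) pairs uniformly, excluding `exclude`
sample_negative_pairs <- function(n, diseases, drugs, exclude_keys) {
  total <- as.numeric(length(diseases)) * length(drugs)
  if (total - length(exclude_keys) < n)
    stop_input("not enough unobserved pairs to sample negatives")
  out <- character(0)
  while (length(out) < n) {
    idx <- sample.int(total, min(2L * (n - length(out)) + 10L, total))
    di <- ((idx - 1L) %% length(diseases)) + 1L
    dr <- ((idx - 1L) %/% length(diseases)) + 1L
    k <- pair_key(diseases[di], drugs[dr])
    k <- setdiff(unique(k), c(exclude_keys, out))
    out <- c(out, k)
  }
  out <- out[seq_len(n)]
  parts <- strsplit(out, "\r", fixed = TRUE)
  data.frame(disease_id = vapply(parts, `[`, "", 1L),
             drug_id = vapply(parts, `[`, "", 2L), row.names = NULL)
}

#' Train/test split of association pairs
#'
#' Random split of the positive drug-disease pairs, stratified by disease,
#' into training and testing portions (80:20 by default). Negative pairs are
#' sampled 1:1 per partition from the unobserved pairs of the disease x drug
#' universe, excluding every positive. Fully seeded.
#'
#' @param positives data.frame with columns `disease_id`, `drug_id`.
#' @param drugs drug identifier universe (e.g. a [drug_vocabulary()]).
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @param diseases disease universe (default the diseases of `positives`).
#' @return object of class `split_plan`: list with `train`, `test`,
#'   `train_negatives`, `test_negatives` data.frames and the seed.
#' @export
split_pairs <- function(positives, drugs, ratio = 0.8, seed = 1L,
                        diseases = NULL) {
  stopifnot(is.data.frame(positives),
            all(c("disease_id", "drug_id") %in% names(positives)))
  if (nrow(positives) < 5L) stop_input("need at least 5 positive pairs")
  if (ratio <= 0 || ratio >= 1) stop_input("ratio must lie in (0, 1)")
  drugs <- as.character(drugs)
  diseases <- as.character(diseases %||% unique(positives$disease_id))
  set.seed(derive_seed(seed, "split"))
  test_idx <- unlist(lapply(split(seq_len(nrow(positives)), positives$disease_id),
                            function(ix) {
    n_test <- round(length(ix) * (1 - ratio))
    if (n_test == 0L || n_test == length(ix)) {
      sample(ix, max(0L, min(length(ix) - 1L, n_test)))
    } else sample(ix, n_test)
  }), use.names = FALSE)
  test <- positives[sort(test_idx), c("disease_id", "drug_id")]
  train <- positives[setdiff(seq_len(nrow(positives)), test_idx),
                     c("disease_id", "drug_id")]
  pos_keys <- pair_key(positives$disease_id, positives$drug_id)
  plan <- list(train = train, test = test,
               train_negatives = sample_negative_pairs(nrow(train), diseases,
                                                       drugs, pos_keys),
               test_negatives = sample_negative_pairs(nrow(test), diseases,
                                                      drugs, pos_keys),
               diseases = diseases, drugs = drugs, ratio = ratio, seed = seed)
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Association split:", nrow(x$train), "train /", nrow(x$test),
      "test positives (ratio", x$ratio, "), 1:1 negatives, seed", x$seed, "\n")
  invisible(x)
}

## build a binary disease x drug matrix from a positive pair table
association_matrix <- function(positives, diseases, drugs) {
  X <- matrix(0, length(diseases), length(drugs),
              dimnames = list(diseases, drugs))
  keep <- positives$disease_id %in% diseases & positives$drug_id %in% drugs
  X[cbind(match(positives$disease_id[keep], diseases),
          match(positives$drug_id[keep], drugs))] <- 1
  X
}

score_pairs <- function(Xhat, pairs, diseases, drugs) {
  Xhat[cbind(match(pairs$disease_id, diseases), match(pairs$drug_id, drugs))]
}

#' Assign positive pairs to cross-validation folds
#'
#' Seeded disjoint partition of the positive pairs into `folds` folds,
#' stratified by disease (each disease's positives are spread as evenly as
#' possible across folds).
#'
#' @param positives data.frame with a `disease_id` column.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels (1..folds) parallel to the rows of
#'   `positives`.
#' @export
cv_folds <- function(positives, folds, seed = 1L) {
  set.seed(derive_seed(seed, "cv-folds"))
  fold_of <- integer(nrow(positives))
  for (ix in split(seq_len(nrow(positives)), positives$disease_id)) {
    fold_of[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  fold_of
}

#' Five-fold cross-validation of the association predictor
#'
#' Partitions the positive pairs into `folds` disjoint folds (stratified by
#' disease). For each fold, a fresh Wasserstein VAE is trained on the
#' association matrix built from the remaining folds (the fused drug
#' features are fixed inputs) and both the held-out positives and the
#' training positives are scored against 1:1 sampled negatives; train and
#' test AUROC are reported per fold.
#'
#' @param positives data.frame of positive pairs (`disease_id`, `drug_id`).
#' @param features fused drug-feature matrix; rownames are the drug
#'   vocabulary.
#' @param drugs drug identifier universe (default `rownames(features)`).
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment, negatives, training).
#' @param weights a [loss_weights()].
#' @param config a [wvae_config()].
#' @param diseases disease universe (default diseases of `positives`).
#' @return object of class `evaluation_report`: data.frame of per-fold
#'   train/test AUROC plus attributes with means, sds and counts.
#' @export
cross_validate <- function(positives, features, drugs = NULL, folds = 5L,
                           seed = 1L, weights = loss_weights(),
                           config = wvae_config(), diseases = NULL) {
  folds <- as.integer(folds)
  if (nrow(positives) < folds) stop_input("need at least one positive per fold")
  drugs <- as.character(drugs %||% rownames(features))
  diseases <- as.character(diseases %||% unique(positives$disease_id))
  fold_of <- cv_folds(positives, folds, seed)
  pos_keys <- pair_key(positives$disease_id, positives$drug_id)
  res <- data.frame(fold = seq_len(folds), train_auroc = NA_real_,
                    test_auroc = NA_real_)
  for (f in seq_len(folds)) {
    train <- positives[fold_of != f, , drop = FALSE]
    test <- positives[fold_of == f, , drop = FALSE]
    if (nrow(test) == 0L || nrow(train) == 0L)
      stop_input("degenerate fold ", f, "; reduce the number of folds")
    X <- association_matrix(train, diseases, drugs)
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("cv-fit", f))
    model <- build_wvae(length(drugs), features, cfg)
    model <- train_wvae(model, X, weights)
    Pn <- normalize_rows(X)
    Xhat <- wvae_forward(model$params, X, model$features, Pn)$Xhat
    set.seed(derive_seed(seed, paste0("cv-neg", f)))
    neg_tr <- sample_negative_pairs(nrow(train), diseases, drugs, pos_keys)
    neg_te <- sample_negative_pairs(nrow(test), diseases, drugs, pos_keys)
    sc_tr <- c(score_pairs(Xhat, train, diseases, drugs),
               score_pairs(Xhat, neg_tr, diseases, drugs))
    sc_te <- c(score_pairs(Xhat, test, diseases, drugs),
               score_pairs(Xhat, neg_te, diseases, drugs))
    res$train_auroc[f] <- auroc(sc_tr, rep(1:0, c(nrow(train), nrow(neg_tr))))
    res$test_auroc[f] <- auroc(sc_te, rep(1:0, c(nrow(test), nrow(neg_te))))
  }
  structure(res,
            class = c("evaluation_report", "data.frame"),
            fold_of = fold_of,
            n_positives = nrow(positives),
            means = c(train = mean(res$train_auroc), test = mean(res$test_auroc)),
            sds = c(train = stats::sd(res$train_auroc),
                    test = stats::sd(res$test_auroc)))
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- attr(x, "means")
  s <- attr(x, "sds")
  cat(nrow(x), "-fold cross-validation over ", attr(x, "n_positives"),
      " positive pairs (1:1 sampled negatives)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("mean train AUROC %.4f (sd %.4f) | mean test AUROC %.4f (sd %.4f)\n",
              m["train"], s["train"], m["test"], s["test"]))
  invisible(x)
}

#' Top candidate drugs for one disease
#'
#' Slice of the prediction table: the `top_k` highest-scoring novel
#' candidates for a disease, with known positives flagged (and not counted
#' against `top_k`).
#'
#' @param model a trained `wvae`.
#' @param x_query binary association matrix with rownames (disease ids).
#' @param disease_id which disease row to report.
#' @param top_k number of novel candidates (default 20).
#' @return a `prediction_table` slice, novel candidates first.
#' @export
rank_report <- function(model, x_query, disease_id, top_k = 20L) {
  if (!disease_id %in% rownames(x_query))
    stop_input("unknown disease: ", disease_id)
  tab <- predict(model, x_query[disease_id, , drop = FALSE], mask_known = TRUE)
  novel <- tab[!tab$known, , drop = FALSE]
  utils::head(novel, top_k)
}
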