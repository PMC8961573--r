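## Vectorised builders for the nine input networks, and the top-level
## fitting function tying the whole pipeline together.

## Tanimoto/Jaccard on the rows of a binary incidence matrix:
## intersection / (|A| + |B| - intersection). Empty rows score 0 everywhere.
incidence_tanimoto <- function(B) {
  B <- as.matrix(B)
  inter <- tcrossprod(B)
  sizes <- rowSums(B)
  denom <- outer(sizes, sizes, "+") - inter
  S <- ifelse(denom > 0, inter / denom, 0)
  dimnames(S) <- list(rownames(B), rownames(B))
  S
}

## incidence matrix (drugs x entities) from a named list of entity sets
sets_to_incidence <- function(sets, vocab, entities) {
  M <- matrix(0L, length(vocab), length(entities),
              dimnames = list(as.character(vocab), entities))
  for (d in names(sets)) {
    hit <- match(sets[[d]], entities)
    M[d, hit[!is.na(hit)]] <- 1L
  }
  M
}

## mean-over-pairs lift of an entity-level similarity to the drug level:
## (A S A^T) / (n_i n_j); drugs with no entities get zero rows
lift_mean <- function(A, S) {
  n <- rowSums(A)
  num <- A %*% S %*% t(A)
  den <- outer(n, n)
  out <- ifelse(den > 0, num / den, 0)
  ## numerical guard: similarity products can exceed 1 by rounding
  pmin(pmax(out, 0), 1)
}

## ATC code-level similarity matrix (leading matched levels / 5)
atc_code_matrix <- function(codes) {
  ok <- grepl("^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$", codes)
  if (!all(ok))
    stop_input("malformed ATC code(s): ", paste(codes[!ok], collapse = ", "))
  lv <- c(1, 3, 4, 5, 7)
  match_lv <- matrix(0, length(codes), length(codes))
  alive <- matrix(TRUE, length(codes), length(codes))
  for (p in lv) {
    pre <- substr(codes, 1, p)
    eq <- outer(pre, pre, "==")
    alive <- alive & eq
    match_lv <- match_lv + alive
  }
  match_lv / 5
}

#' Assemble the nine drug networks from a raw bundle
#'
#' Builds the six homogeneous drug-drug networks — chemical structure
#' (Tanimoto on fingerprints), side-effect profile (Tanimoto on sets),
#' target sequence (mean normalised Smith-Waterman over target pairs),
#' biological function (mean Wang gene-pair similarity), therapeutic class
#' (mean ATC code-pair similarity) and the interaction graph — and the three
#' bipartite networks (drug-gene, drug-side-effect, drug-disease). Drugs
#' with no data in a modality get zero rows in that network.
#'
#' @param bundle a `drug_bundle` (see [generate_bundle()], [read_bundle()]).
#' @param verbose emit per-network progress messages (default `FALSE`).
#' @return named list of six [homogeneous_network()] and three
#'   [bipartite_network()] objects, in the pipeline's canonical order
#'   `structure`, `side_effect`, `target_sequence`, `go_function`, `atc`,
#'   `interaction`, `drug_gene`, `drug_side_effect`, `drug_disease`.
#' @export
similarity_networks <- function(bundle, verbose = FALSE) {
  vocab <- bundle$vocab
  drugs <- as.character(vocab)
  say <- function(...) if (verbose) message(...)

  say("structure network (Tanimoto on fingerprints)")
  structure_net <- homogeneous_network(incidence_tanimoto(bundle$fingerprints),
                                       vocab, kind = "structure")

  say("side-effect similarity network")
  se_ids <- sort(unique(unlist(bundle$side_effects, use.names = FALSE)))
  se_inc <- sets_to_incidence(bundle$side_effects, vocab, se_ids)
  side_effect_net <- homogeneous_network(incidence_tanimoto(se_inc), vocab,
                                         kind = "side_effect")

  say("target-sequence network (Smith-Waterman)")
  gene_ids <- sort(unique(unlist(bundle$targets, use.names = FALSE)))
  used <- intersect(gene_ids, names(bundle$gene_sequences))
  tg_inc <- sets_to_incidence(lapply(bundle$targets, intersect, used),
                              vocab, used)
  seq_sim <- sequence_similarity_matrix(bundle$gene_sequences[used])
  target_net <- homogeneous_network(lift_mean(tg_inc, seq_sim), vocab,
                                    kind = "target_sequence")

  say("functional network (Wang GO similarity)")
  dag <- go_dag(bundle$go_edges)
  annotated <- used[vapply(used, function(g)
    length(bundle$annotations[[g]] %||% character(0)) > 0, logical(1))]
  gene_sim <- gene_similarity_matrix(annotated, bundle$annotations, dag)
  go_inc <- sets_to_incidence(lapply(bundle$targets, intersect, annotated),
                              vocab, annotated)
  go_net <- homogeneous_network(lift_mean(go_inc, gene_sim), vocab,
                                kind = "go_function")

  say("therapeutic-class network (ATC)")
  codes <- sort(unique(unlist(bundle$atc, use.names = FALSE)))
  atc_inc <- sets_to_incidence(bundle$atc, vocab, codes)
  atc_net <- homogeneous_network(lift_mean(atc_inc, atc_code_matrix(codes)),
                                 vocab, kind = "atc")

  say("interaction network")
  A <- matrix(0, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  ia <- bundle$interactions
  if (nrow(ia)) {
    A[cbind(match(ia$drug_a, drugs), match(ia$drug_b, drugs))] <- 1
    A[cbind(match(ia$drug_b, drugs), match(ia$drug_a, drugs))] <- 1
  }
  interaction_net <- homogeneous_network(A, vocab, kind = "interaction",
                                         similarity = FALSE)

  say("bipartite networks")
  assoc <- bundle$associations
  dis_inc <- matrix(0L, length(drugs), length(bundle$diseases),
                    dimnames = list(drugs, bundle$diseases))
  if (nrow(assoc))
    dis_inc[cbind(match(assoc$drug_id, drugs),
                  match(assoc$disease_id, bundle$diseases))] <- 1L
  list(structure = structure_net,
       side_effect = side_effect_net,
       target_sequence = target_net,
       go_function = go_net,
       atc = atc_net,
       interaction = interaction_net,
       drug_gene = bipartite_network(tg_inc, vocab, used, kind = "drug_gene"),
       drug_side_effect = bipartite_network(se_inc, vocab, se_ids,
                                            kind = "drug_side_effect"),
       drug_disease = bipartite_network(dis_inc, vocab, bundle$diseases,
                                        kind = "drug_disease"))
}

#' @rdname drug_go_similarity
#' @param genes gene identifiers to compare pairwise.
#' @return `gene_similarity_matrix`: symmetric matrix of best-match-average
#'   Wang similarities over the genes' annotation sets.
#' @export
gene_similarity_matrix <- function(genes, annotations, dag) {
  genes <- as.character(genes)
  terms <- sort(unique(unlist(annotations[genes], use.names = FALSE)))
  TS <- go_term_similarity_matrix(dag, terms)
  G <- sets_to_incidence(annotations[genes], genes, terms)
  ## best match of each term against each gene's term set
  B1 <- matrix(0, length(terms), length(genes),
               dimnames = list(terms, genes))
  for (j in seq_along(genes)) {
    tj <- which(G[j, ] == 1L)
    B1[, j] <- apply(TS[, tj, drop = FALSE], 1L, max)
  }
  GB <- G %*% B1 # (g, h): sum over g's terms of best match against h
  nt <- rowSums(G)
  S <- (GB + t(GB)) / outer(nt, nt, "+")
  diag(S) <- 1
  pmin(pmax(S, 0), 1)
}

#' Fit the drug-repositioning model
#'
#' End-to-end fit: assembles the nine networks from the raw bundle, embeds
#' each as a PPMI matrix via random-walk co-occurrence, fuses them with the
#' multimodal autoencoder, and trains the Wasserstein VAE on the observed
#' disease-drug association rows. Returns a fitted model object from which
#' candidate drugs are ranked with [predict.repositioner()].
#'
#' @param bundle a `drug_bundle`.
#' @param omega,walk_length,rwr_bipartite random-walk settings
#'   (see [embed_all()]).
#' @param mae a [mae_config()].
#' @param wvae a [wvae_config()].
#' @param weights a [loss_weights()].
#' @param seed optional master seed; when given it reseeds both autoencoder
#'   configs so one integer reproduces the whole fit.
#' @param verbose stage progress messages (default `TRUE`).
#' @return object of class `repositioner`: the fitted components
#'   (`networks`, `ppmi`, `mae`, `features`, `wvae`), the association matrix
#'   `X`, vocabularies and configuration.
#' @export
fit_repositioner <- function(bundle, omega = 0.5, walk_length = 3L,
                             rwr_bipartite = TRUE,
                             mae = mae_config(), wvae = wvae_config(),
                             weights = loss_weights(), seed = NULL,
                             verbose = TRUE) {
  stopifnot(inherits(bundle, "drug_bundle"))
  if (!is.null(seed)) {
    mae$seed <- derive_seed(seed, "mae")
    wvae$seed <- derive_seed(seed, "wvae")
  }
  say <- function(...) if (verbose) message(...)
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(stage) {
    timings[stage] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }

  say("[1/5] assembling drug networks")
  networks <- similarity_networks(bundle, verbose = FALSE)
  tick("networks")

  say("[2/5] random-walk PPMI embedding")
  ppmis <- embed_all(networks, omega = omega, walk_length = walk_length,
                     rwr_bipartite = rwr_bipartite)
  tick("embedding")

  say("[3/5] multimodal autoencoder fusion")
  scaled <- scale_inputs(ppmis)
  mae_model <- build_mae(mae, n_networks = length(scaled),
                         n_drugs = length(bundle$vocab))
  mae_model <- train_mae(mae_model, scaled)
  features <- extract_features(mae_model, scaled)
  rownames(features) <- as.character(bundle$vocab)
  tick("fusion")

  say("[4/5] Wasserstein VAE on association rows")
  X <- association_matrix(bundle$associations, bundle$diseases,
                          as.character(bundle$vocab))
  wvae_model <- build_wvae(length(bundle$vocab), features, wvae)
  wvae_model <- train_wvae(wvae_model, X, weights)
  tick("prediction")

  say("[5/5] done")
  structure(list(vocab = bundle$vocab, diseases = bundle$diseases,
                 networks = networks, ppmi = ppmis, scaled = scaled,
                 mae = mae_model, features = features, wvae = wvae_model,
                 X = X, weights = weights,
                 settings = list(omega = omega, walk_length = walk_length,
                                 rwr_bipartite = rwr_bipartite, seed = seed),
                 timings = timings),
            class = "repositioner")
}

#' @export
print.repositioner <- function(x, ...) {
  cat("Drug-repositioning model\n")
  cat("  ", length(x$vocab), " drugs, ", length(x$diseases), " diseases, ",
      sum(x$X), " known associations\n", sep = "")
  cat("  networks:", paste(names(x$networks), collapse = ", "), "\n")
  cat("  fused features: d =", ncol(x$features),
      "| MAE final loss", format(utils::tail(x$mae$history$loss, 1), digits = 5),
      "\n")
  cat("  predictor: ot_mode =", x$weights$ot_mode,
      "| final loss", format(utils::tail(x$wvae$history$loss, 1), digits = 5),
      "\n")
  invisible(x)
}

#' @export
summary.repositioner <- function(object, top_k = 5L, ...) {
  print(object)
  cat("\nTop", top_k, "novel candidates per disease (first 3 diseases):\n")
  for (d in utils::head(object$diseases, 3L)) {
    tab <- rank_report(object$wvae, object$X, d, top_k = top_k)
    cat(" ", d, ": ",
        paste(sprintf("%s (%.3f)", tab$drug_id, tab$score), collapse = ", "),
        "\n", sep = "")
  }
  invisible(object)
}

#' Rank candidate drugs for diseases
#'
#' @param object a fitted `repositioner`.
#' @param disease disease identifier(s); default all diseases of the fit.
#' @param top_k keep the top k rows per disease (default all).
#' @param mask_known flag drugs already associated in the training table.
#' @param ... unused.
#' @return a `prediction_table` data.frame
#'   (`disease_id`, `drug_id`, `score`, `rank`, `known`).
#' @export
predict.repositioner <- function(object, disease = NULL, top_k = Inf,
                                 mask_known = TRUE, ...) {
  disease <- disease %||% object$diseases
  miss <- setdiff(disease, rownames(object$X))
  if (length(miss)) stop_input("unknown disease(s): ", paste(miss, collapse = ", "))
  tab <- predict(object$wvae, object$X[disease, , drop = FALSE],
                 mask_known = mask_known)
  if (is.finite(top_k))
    tab <- do.call(rbind, lapply(split(tab, tab$disease_id), utils::head,
                                 n = top_k))
  rownames(tab) <- NULL
  class(tab) <- c("prediction_table", "data.frame")
  tab
}

#' @export
plot.repositioner <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$mae$history$epoch, x$mae$history$loss, type = "l",
       xlab = "epoch", ylab = "reconstruction loss (BCE)",
       main = "Network fusion")
  plot(x$wvae$history$epoch, x$wvae$history$loss, type = "l",
       xlab = "epoch", ylab = "composite loss",
       main = "Association predictor")
  invisible(x)
}
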