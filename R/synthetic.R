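#' Synthetic benchmark configuration
#'
#' Study conditions for the planted-structure benchmark: drugs and diseases
#' are partitioned into clusters; every per-drug modality (fingerprint,
#' target genes, side effects, ATC codes, target protein sequences, and the
#' drug-drug interaction graph) carries the cluster signal with realistic
#' corruption, and the true drug-disease associations are the within-cluster
#' pairs, observed through a symmetric noise flip.
#'
#' @param n_drugs,n_genes,n_side_effects,n_diseases population sizes
#'   (defaults 300, 400, 500, 30).
#' @param n_clusters number of planted clusters (default 6).
#' @param within_cluster_edge_prob,between_cluster_edge_prob interaction
#'   edge probabilities (defaults 0.3 and 0.02).
#' @param association_noise probability of flipping a drug-disease pair
#'   (default 0.05).
#' @param fingerprint_length fingerprint width in bits (default 166).
#' @param seq_length protein sequence length range (default 80-150).
#' @param seed integer seed (default 7).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 300L, n_genes = 400L,
                             n_side_effects = 500L, n_diseases = 30L,
                             n_clusters = 6L,
                             within_cluster_edge_prob = 0.3,
                             between_cluster_edge_prob = 0.02,
                             association_noise = 0.05,
                             fingerprint_length = 166L,
                             seq_length = c(80L, 150L), seed = 7L) {
  stopifnot(n_drugs >= n_clusters, n_diseases >= n_clusters, n_clusters >= 1,
            n_genes >= n_clusters, n_side_effects >= n_clusters,
            within_cluster_edge_prob >= 0, within_cluster_edge_prob <= 1,
            between_cluster_edge_prob >= 0, between_cluster_edge_prob <= 1,
            association_noise >= 0, association_noise <= 1,
            fingerprint_length >= 1, length(seq_length) == 2L,
            seq_length[1] >= 10L, seq_length[2] >= seq_length[1])
  structure(as.list(environment()), class = "synthetic_config")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  chars
}

#' Generate the synthetic drug-repositioning benchmark
#'
#' Produces all nine raw inputs in memory (write them with
#' [write_bundle()]): drug fingerprints, drug-target gene sets, one protein
#' sequence per gene, GO annotations over a cluster-aligned toy DAG, ATC
#' codes, side-effect sets, a drug-drug interaction edge list, and the
#' observed drug-disease association table — together with the ground truth
#' (cluster maps and pre-noise true pairs). Member modalities are noisy
#' copies of cluster prototypes: fingerprint bits flip at 5%, side-effect
#' items drop at 20% with random replacements, protein sequences mutate at
#' 5% within a cluster against 30% between cluster roots, and one drug in
#' five carries a second, off-cluster ATC code. Fully determined by
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `drug_bundle`: list with `vocab`, `fingerprints`,
#'   `targets`, `gene_sequences`, `annotations`, `go_edges`, `atc`,
#'   `side_effects`, `interactions`, `associations`, `diseases`, `truth`
#'   and `config`.
#' @export
generate_bundle <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, "synthetic"))
  k <- cfg$n_clusters
  drugs <- sprintf("DR%04d", seq_len(cfg$n_drugs))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ses <- sprintf("SE%04d", seq_len(cfg$n_side_effects))
  diseases <- sprintf("DIS%03d", seq_len(cfg$n_diseases))
  drug_cluster <- stats::setNames(((seq_len(cfg$n_drugs) - 1L) %% k) + 1L, drugs)
  gene_cluster <- stats::setNames(((seq_len(cfg$n_genes) - 1L) %% k) + 1L, genes)
  se_cluster <- stats::setNames(((seq_len(cfg$n_side_effects) - 1L) %% k) + 1L, ses)
  disease_cluster <- stats::setNames(((seq_len(cfg$n_diseases) - 1L) %% k) + 1L,
                                     diseases)

  ## fingerprints: cluster prototypes, 5% member bit flips
  proto_fp <- matrix(stats::rbinom(k * cfg$fingerprint_length, 1L, 0.3), k)
  fp <- matrix(0L, cfg$n_drugs, cfg$fingerprint_length,
               dimnames = list(drugs, NULL))
  for (i in seq_len(cfg$n_drugs)) {
    bits <- proto_fp[drug_cluster[i], ]
    flip <- stats::runif(cfg$fingerprint_length) < 0.05
    fp[i, ] <- ifelse(flip, 1L - bits, bits)
  }

  ## protein sequences: global root -> 30%-mutated cluster roots ->
  ## 5%-mutated gene sequences (shared lengths so similarity reflects descent)
  len <- sample(seq(cfg$seq_length[1], cfg$seq_length[2]), 1L)
  root <- sample(AA20, len, replace = TRUE)
  cluster_root <- lapply(seq_len(k), function(c) mutate_seq(root, 0.30))
  gene_sequences <- stats::setNames(vapply(genes, function(g) {
    paste(mutate_seq(cluster_root[[gene_cluster[g]]], 0.05), collapse = "")
  }, character(1)), genes)

  ## drug targets: 2-4 genes, 90% from the own-cluster pool
  gene_pool <- split(genes, gene_cluster)
  targets <- stats::setNames(lapply(drugs, function(d) {
    nt <- sample(2:4, 1L)
    own <- stats::runif(nt) < 0.9
    c(sample(gene_pool[[drug_cluster[d]]], sum(own)),
      if (any(!own)) sample(setdiff(genes, gene_pool[[drug_cluster[d]]]),
                            sum(!own)))
  }), drugs)

  ## GO: one root, one branch per cluster, 6 leaves per branch
  branch <- sprintf("GO:%07d", seq_len(k) + 1L)
  leaves <- lapply(seq_len(k), function(c)
    sprintf("GO:%07d", 100L * c + seq_len(6L)))
  go_edges <- rbind(
    data.frame(child = branch, parent = "GO:0000001", relation = "is_a"),
    do.call(rbind, lapply(seq_len(k), function(c) {
      data.frame(child = leaves[[c]], parent = branch[c],
                 relation = sample(c("is_a", "part_of"), 6L, TRUE,
                                   prob = c(0.7, 0.3)))
    }))
  )
  annotations <- stats::setNames(lapply(genes, function(g) {
    c <- gene_cluster[g]
    terms <- sample(leaves[[c]], sample(2:4, 1L))
    if (stats::runif(1) < 0.1) {
      other <- sample(setdiff(seq_len(k), c), 1L)
      terms <- c(terms, sample(leaves[[other]], 1L))
    }
    terms
  }), genes)

  ## ATC: cluster stem shares the first four levels; 20% of drugs carry a
  ## second off-cluster code
  atc <- stats::setNames(lapply(drugs, function(d) {
    c <- drug_cluster[d]
    code <- sprintf("%s01AA%02d", LETTERS[c], sample(1:99, 1L))
    if (stats::runif(1) < 0.2) {
      other <- sample(setdiff(seq_len(k), c), 1L)
      code <- c(code, sprintf("%s01AA%02d", LETTERS[other], sample(1:99, 1L)))
    }
    code
  }), drugs)

  ## side effects: prototype set of 20 per cluster; members drop 20% and
  ## pick up 3 random effects
  se_pool <- split(ses, se_cluster)
  proto_se <- lapply(seq_len(k), function(c)
    sample(se_pool[[c]], min(20L, length(se_pool[[c]]))))
  side_effects <- stats::setNames(lapply(drugs, function(d) {
    s <- proto_se[[drug_cluster[d]]]
    s <- s[stats::runif(length(s)) >= 0.2]
    unique(c(s, sample(ses, 3L)))
  }), drugs)

  ## drug-drug interactions: stochastic block model on the clusters
  pairs <- utils::combn(cfg$n_drugs, 2L)
  same <- drug_cluster[pairs[1L, ]] == drug_cluster[pairs[2L, ]]
  p_edge <- ifelse(same, cfg$within_cluster_edge_prob,
                   cfg$between_cluster_edge_prob)
  keep <- stats::runif(ncol(pairs)) < p_edge
  interactions <- data.frame(drug_a = drugs[pairs[1L, keep]],
                             drug_b = drugs[pairs[2L, keep]])

  ## associations: within-cluster pairs, symmetric noise flip
  grid <- expand.grid(disease_id = diseases, drug_id = drugs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  is_true <- disease_cluster[grid$disease_id] == drug_cluster[grid$drug_id]
  flip <- stats::runif(nrow(grid)) < cfg$association_noise
  observed <- xor(is_true, flip)
  associations <- grid[observed, , drop = FALSE]
  rownames(associations) <- NULL

  truth <- list(drug_cluster = drug_cluster,
                disease_cluster = disease_cluster,
                true_pairs = grid[is_true, , drop = FALSE])
  rownames(truth$true_pairs) <- NULL

  structure(list(vocab = drug_vocabulary(drugs), fingerprints = fp,
                 targets = targets, gene_sequences = gene_sequences,
                 annotations = annotations, go_edges = go_edges, atc = atc,
                 side_effects = side_effects, interactions = interactions,
                 associations = associations, diseases = diseases,
                 truth = truth, config = cfg),
            class = "drug_bundle")
}

#' @export
print.drug_bundle <- function(x, ...) {
  cat("Drug data bundle:", length(x$vocab), "drugs,",
      length(x$gene_sequences), "genes,", length(x$diseases), "diseases,",
      nrow(x$associations), "observed associations\n")
  if (!is.null(x$truth))
    cat("  planted clusters:", max(x$truth$drug_cluster), "\n")
  invisible(x)
}

#' Hold out a fraction of true associations
#'
#' Removes a seeded fraction of the genuinely true associations (pairs that
#' are both planted and observed) from the association table, for recovery
#' testing: the pipeline is trained on the visible table and asked to rank
#' the hidden pairs highly.
#'
#' @param bundle a `drug_bundle` with ground truth.
#' @param fraction fraction of true observed pairs to hide (in (0, 1)).
#' @param seed integer seed.
#' @return list with `bundle` (associations reduced to the visible pairs),
#'   `visible` and `hidden` pair data.frames.
#' @export
holdout_associations <- function(bundle, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_input("fraction must lie in (0, 1)")
  if (is.null(bundle$truth)) stop_input("bundle carries no ground truth")
  obs <- bundle$associations
  obs_keys <- pair_key(obs$disease_id, obs$drug_id)
  true_keys <- pair_key(bundle$truth$true_pairs$disease_id,
                        bundle$truth$true_pairs$drug_id)
  eligible <- which(obs_keys %in% true_keys)
  set.seed(derive_seed(seed, "holdout"))
  hide <- sample(eligible, round(length(eligible) * fraction))
  hidden <- obs[sort(hide), , drop = FALSE]
  visible <- obs[setdiff(seq_len(nrow(obs)), hide), , drop = FALSE]
  rownames(hidden) <- rownames(visible) <- NULL
  bundle$associations <- visible
  list(bundle = bundle, visible = visible, hidden = hidden)
}
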