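## Readers and writers for the plain-text interchange formats. Every table
## is TSV with a header row; sequences are FASTA. A manifest JSON records the
## configuration and seed of whatever produced the directory.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## strict TSV reader: checks the header and per-line column counts, naming
## the offending file and line on error
read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop_input("missing input file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop_input(path, ": empty file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, columns))
    stop_input(path, ": expected columns ", paste(columns, collapse = ", "),
               " but found ", paste(header, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(columns))
  if (length(bad))
    stop_input(path, ": line ", bad[1L] + 1L, " has ", lengths(parts)[bad[1L]],
               " fields where ", length(columns), " were expected")
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- as.data.frame(stats::setNames(replicate(length(columns),
                                                   character(0),
                                                   simplify = FALSE), columns))
  names(out) <- columns
  out
}

#' Write a drug data bundle to a directory
#'
#' Serialises the nine raw inputs in their interchange formats:
#' `drugs.tsv`, `diseases.tsv`, `fingerprints.tsv` (drug_id + bitstring),
#' `drug_targets.tsv`, `protein_sequences.fasta`, `gene_go.tsv`,
#' `go_dag.tsv`, `atc_codes.tsv`, `side_effects.tsv`,
#' `drug_interactions.tsv`, `associations.tsv`, plus `manifest.json` (the
#' generating configuration, when present) and — for synthetic bundles —
#' the ground-truth cluster maps and pre-noise associations under
#' `truth_*.tsv`. Output is byte-stable for a fixed bundle.
#'
#' @param bundle a `drug_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  drugs <- as.character(bundle$vocab)
  write_tsv(data.frame(drug_id = drugs), p("drugs.tsv"))
  write_tsv(data.frame(disease_id = bundle$diseases), p("diseases.tsv"))
  write_tsv(data.frame(drug_id = drugs,
                       bits = apply(bundle$fingerprints, 1L, paste,
                                    collapse = "")),
            p("fingerprints.tsv"))
  edges <- function(lst, col) {
    data.frame(drug_id = rep(names(lst), lengths(lst)),
               x = unlist(lst, use.names = FALSE)) |>
      stats::setNames(c("drug_id", col))
  }
  write_tsv(edges(bundle$targets, "gene_id"), p("drug_targets.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(bundle$gene_sequences), p("protein_sequences.fasta"))
  write_tsv(edges(bundle$annotations, "go_term") |>
              stats::setNames(c("gene", "go_term")), p("gene_go.tsv"))
  write_tsv(bundle$go_edges, p("go_dag.tsv"))
  write_tsv(edges(bundle$atc, "atc_code"), p("atc_codes.tsv"))
  write_tsv(edges(bundle$side_effects, "side_effect_id"), p("side_effects.tsv"))
  write_tsv(bundle$interactions, p("drug_interactions.tsv"))
  write_tsv(bundle$associations, p("associations.tsv"))
  if (!is.null(bundle$config)) {
    jsonlite::write_json(unclass(bundle$config), p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    write_tsv(data.frame(drug_id = names(tr$drug_cluster),
                         cluster = unname(tr$drug_cluster)),
              p("truth_drug_clusters.tsv"))
    write_tsv(data.frame(disease_id = names(tr$disease_cluster),
                         cluster = unname(tr$disease_cluster)),
              p("truth_disease_clusters.tsv"))
    write_tsv(tr$true_pairs, p("truth_associations.tsv"))
  }
  invisible(dir)
}

#' Read a drug data bundle from a directory
#'
#' Inverse of [write_bundle()]. Every file is validated line by line (a
#' malformed row aborts with the file and line number); identifiers are
#' cross-checked against `drugs.tsv` — rows referring to drugs absent from
#' the vocabulary are excluded with a warning.
#'
#' @param dir directory written by [write_bundle()] (or assembled by hand in
#'   the same formats).
#' @return a `drug_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  drugs <- read_tsv_checked(p("drugs.tsv"), "drug_id")$drug_id
  vocab <- drug_vocabulary(drugs)
  diseases <- read_tsv_checked(p("diseases.tsv"), "disease_id")$disease_id
  check_drugs <- function(df, file) {
    bad <- !df$drug_id %in% drugs
    if (any(bad)) {
      warning(file, ": excluding ", sum(bad), " row(s) with drugs not in the",
              " vocabulary (e.g. ", df$drug_id[bad][1L], ")")
      df <- df[!bad, , drop = FALSE]
    }
    df
  }
  fp_tab <- check_drugs(read_tsv_checked(p("fingerprints.tsv"),
                                         c("drug_id", "bits")),
                        "fingerprints.tsv")
  widths <- unique(nchar(fp_tab$bits))
  if (length(widths) > 1L)
    stop_input("fingerprints.tsv: inconsistent fingerprint lengths: ",
               paste(widths, collapse = ", "))
  if (any(grepl("[^01]", fp_tab$bits)))
    stop_input("fingerprints.tsv: fingerprints must be 0/1 bitstrings")
  fp <- matrix(0L, length(drugs), if (length(widths)) widths else 0L,
               dimnames = list(drugs, NULL))
  for (i in seq_len(nrow(fp_tab))) {
    fp[fp_tab$drug_id[i], ] <-
      as.integer(strsplit(fp_tab$bits[i], "")[[1L]])
  }
  as_sets <- function(df, key = "drug_id", universe = drugs) {
    out <- stats::setNames(vector("list", length(universe)), universe)
    sp <- split(df[[2L]], df[[key]])
    out[names(sp)] <- lapply(sp, unique)
    out[vapply(out, is.null, logical(1))] <- list(character(0))
    out
  }
  targets <- as_sets(check_drugs(read_tsv_checked(p("drug_targets.tsv"),
                                                  c("drug_id", "gene_id")),
                                 "drug_targets.tsv"))
  seqs <- Biostrings::readAAStringSet(p("protein_sequences.fasta"))
  gene_sequences <- stats::setNames(as.character(seqs), names(seqs))
  go_tab <- read_tsv_checked(p("gene_go.tsv"), c("gene", "go_term"))
  annotations <- stats::setNames(lapply(split(go_tab$go_term, go_tab$gene),
                                        unique),
                                 names(split(go_tab$go_term, go_tab$gene)))
  go_edges <- read_tsv_checked(p("go_dag.tsv"), c("child", "parent", "relation"))
  atc <- as_sets(check_drugs(read_tsv_checked(p("atc_codes.tsv"),
                                              c("drug_id", "atc_code")),
                             "atc_codes.tsv"))
  side_effects <- as_sets(check_drugs(
    read_tsv_checked(p("side_effects.tsv"), c("drug_id", "side_effect_id")),
    "side_effects.tsv"))
  inter <- read_tsv_checked(p("drug_interactions.tsv"), c("drug_a", "drug_b"))
  bad <- !(inter$drug_a %in% drugs & inter$drug_b %in% drugs)
  if (any(bad)) {
    warning("drug_interactions.tsv: excluding ", sum(bad),
            " row(s) with unknown drugs")
    inter <- inter[!bad, , drop = FALSE]
  }
  assoc <- check_drugs(read_tsv_checked(p("associations.tsv"),
                                        c("disease_id", "drug_id")),
                       "associations.tsv")
  truth <- NULL
  if (file.exists(p("truth_drug_clusters.tsv"))) {
    dc <- read_tsv_checked(p("truth_drug_clusters.tsv"), c("drug_id", "cluster"))
    sc <- read_tsv_checked(p("truth_disease_clusters.tsv"),
                           c("disease_id", "cluster"))
    tp <- read_tsv_checked(p("truth_associations.tsv"),
                           c("disease_id", "drug_id"))
    truth <- list(drug_cluster = stats::setNames(as.integer(dc$cluster),
                                                 dc$drug_id),
                  disease_cluster = stats::setNames(as.integer(sc$cluster),
                                                    sc$disease_id),
                  true_pairs = tp)
  }
  config <- NULL
  if (file.exists(p("manifest.json"))) {
    config <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  }
  structure(list(vocab = vocab, fingerprints = fp, targets = targets,
                 gene_sequences = gene_sequences, annotations = annotations,
                 go_edges = go_edges, atc = atc, side_effects = side_effects,
                 interactions = inter, associations = assoc,
                 diseases = diseases, truth = truth, config = config),
            class = "drug_bundle")
}
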