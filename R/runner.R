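## Disk-backed pipeline runner: one cached artifact per stage, a manifest
## sufficient to reproduce the run, and TSV/JSON outputs.

settings_key <- function(settings) {
  jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA)
}

input_hashes <- function(input_dir) {
  files <- sort(list.files(input_dir, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- basename(files)
  h
}

## load a cached stage if its key matches and nothing upstream changed
stage_cache <- function(cache_dir, name, key, dirty, compute) {
  path <- file.path(cache_dir, paste0(name, ".rds"))
  if (!dirty && file.exists(path)) {
    stored <- readRDS(path)
    if (identical(stored$key, key)) {
      return(list(value = stored$value, dirty = FALSE))
    }
  }
  value <- compute()
  saveRDS(list(key = key, value = value), path)
  list(value = value, dirty = TRUE)
}

#' Run the full pipeline against a directory of raw inputs
#'
#' Reads the bundle, executes network assembly, embedding, fusion,
#' prediction and (optionally) cross-validated evaluation, and writes the
#' ranked prediction table, an evaluation report and a run manifest to
#' `output_dir`. Each stage is cached under `output_dir/cache`, keyed on the
#' input file hashes and the settings: re-running with identical inputs and
#' configuration reuses completed stages, and deleting one cache file
#' recomputes exactly that stage and its descendants.
#'
#' @param input_dir directory in the [write_bundle()] layout.
#' @param output_dir output directory (created if needed).
#' @param omega,walk_length,rwr_bipartite,mae,wvae,weights,seed as in
#'   [fit_repositioner()].
#' @param evaluate run five-fold cross-validation and write the report
#'   (default `TRUE`).
#' @param folds cross-validation folds (default 5).
#' @param top_k rows per disease kept in `predictions.tsv` (default all).
#' @param verbose stage progress (default `TRUE`).
#' @return the fitted `repositioner`, invisibly, with the evaluation report
#'   (if any) attached as `$evaluation`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         omega = 0.5, walk_length = 3L, rwr_bipartite = TRUE,
                         mae = mae_config(), wvae = wvae_config(),
                         weights = loss_weights(), seed = NULL,
                         evaluate = TRUE, folds = 5L, top_k = Inf,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(output_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  if (!is.null(seed)) {
    mae$seed <- derive_seed(seed, "mae")
    wvae$seed <- derive_seed(seed, "wvae")
  }
  settings <- list(omega = omega, walk_length = walk_length,
                   rwr_bipartite = rwr_bipartite, mae = unclass(mae),
                   wvae = unclass(wvae), weights = unclass(weights),
                   seed = seed)
  hashes <- input_hashes(input_dir)
  key <- paste0(settings_key(settings), "|", paste(hashes, collapse = ""))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[3]
    v <- expr()
    timings[stage] <<- round(proc.time()[3] - t0, 3)
    v
  }

  bundle <- read_bundle(input_dir)
  dirty <- FALSE

  say("[similarity] assembling networks")
  st <- clock("similarity", function()
    stage_cache(cache_dir, "networks", key, dirty,
                function() similarity_networks(bundle)))
  networks <- st$value; dirty <- st$dirty

  say("[embed] random-walk PPMI")
  st <- clock("embed", function()
    stage_cache(cache_dir, "ppmi", key, dirty, function()
      embed_all(networks, omega, walk_length, rwr_bipartite)))
  ppmis <- st$value; dirty <- st$dirty

  say("[fuse] multimodal autoencoder")
  st <- clock("fuse", function()
    stage_cache(cache_dir, "fusion", key, dirty, function() {
      scaled <- scale_inputs(ppmis)
      m <- train_mae(build_mae(mae, length(scaled), length(bundle$vocab)),
                     scaled)
      f <- extract_features(m, scaled)
      rownames(f) <- as.character(bundle$vocab)
      list(mae = m, features = f, scaled = scaled)
    }))
  fusion <- st$value; dirty <- st$dirty

  say("[predict] Wasserstein VAE")
  X <- association_matrix(bundle$associations, bundle$diseases,
                          as.character(bundle$vocab))
  st <- clock("predict", function()
    stage_cache(cache_dir, "wvae", key, dirty, function()
      train_wvae(build_wvae(length(bundle$vocab), fusion$features, wvae),
                 X, weights)))
  wvae_model <- st$value; dirty <- st$dirty

  fit <- structure(list(vocab = bundle$vocab, diseases = bundle$diseases,
                        networks = networks, ppmi = ppmis,
                        scaled = fusion$scaled, mae = fusion$mae,
                        features = fusion$features, wvae = wvae_model, X = X,
                        weights = weights,
                        settings = settings[c("omega", "walk_length",
                                              "rwr_bipartite", "seed")],
                        timings = timings),
                   class = "repositioner")

  tab <- predict(fit, top_k = top_k)
  write_tsv(tab, file.path(output_dir, "predictions.tsv"))

  if (evaluate) {
    say("[evaluate] ", folds, "-fold cross-validation")
    report <- clock("evaluate", function()
      cross_validate(bundle$associations, fusion$features,
                     drugs = as.character(bundle$vocab), folds = folds,
                     seed = seed %||% wvae$seed, weights = weights,
                     config = wvae, diseases = bundle$diseases))
    fit$evaluation <- report
    write_tsv(as.data.frame(report), file.path(output_dir, "evaluation.tsv"))
    jsonlite::write_json(
      list(folds = folds,
           mean_train_auroc = unname(attr(report, "means")["train"]),
           mean_test_auroc = unname(attr(report, "means")["test"]),
           sd_test_auroc = unname(attr(report, "sds")["test"]),
           n_positives = attr(report, "n_positives")),
      file.path(output_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }

  fit$timings <- timings
  manifest <- list(package_version = as.character(utils::packageVersion("otrepo")),
                   settings = settings, input_hashes = as.list(hashes),
                   stage_seconds = as.list(timings))
  tmp <- file.path(output_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(output_dir, "run_manifest.json"))
  invisible(fit)
}
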