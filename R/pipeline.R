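#' Default pipeline configuration
#'
#' The configuration consumed by [run_pipeline()]: one global `seed` fans
#' out to per-stage seeds by fixed offsets (+1 simulation, +2 split, +3
#' training, +4 enrichment), so each stage is independently reproducible.
#' Either `simulate` holds [sim_config()] overrides, or `inputs` names the
#' corpus files (fingerprint TSV, compound/GP signature GCTs, pathway GMT,
#' optional truth TSV).  `train` overrides the encoder/optimizer settings
#' and `enrichment` the GSEA settings.
#'
#' The default training configuration is sized for the desk-scale synthetic
#' corpus (smaller encoders, a higher learning rate and smaller minibatches
#' than the full-scale defaults of [moable()], which are tuned for corpora
#' of hundreds of thousands of signatures).
#'
#' @param seed global integer seed.
#' @return Nested list of pipeline settings.
#' @export
default_pipeline_config <- function(seed = 7L) {
  list(seed = as.integer(seed),
       simulate = list(),
       split = list(fractions = c(0.7, 0.15, 0.15)),
       train = list(hidden_str = c(512, 256), hidden_sig = c(512, 256),
                    output_dim = 256, margin = 1, learning_rate = 1e-3,
                    batch_size = 128, max_epochs = 200, patience = 25,
                    negative = "random_in_batch"),
       enrichment = list(n_perm = 1000, weight_p = 1, fdr_threshold = 0.1,
                         min_size = 5, max_size = 500))
}

.check_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config schema error: field 'seed' is missing")
  known <- c("seed", "simulate", "inputs", "split", "train", "enrichment")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("config schema error: unknown field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$inputs)) {
    req <- c(fingerprints = "fingerprint TSV",
             compound_signatures = "compound signature GCT",
             gp_signatures = "GP signature GCT",
             pathways = "pathway GMT")
    for (f in names(req))
      if (is.null(cfg$inputs[[f]]))
        stop("config schema error: field 'inputs$", f, "' (", req[f],
             " path) is required")
    for (f in names(req))
      if (!file.exists(cfg$inputs[[f]]))
        stop("missing input: ", f, " file '", cfg$inputs[[f]],
             "' does not exist")
    if (!is.null(cfg$inputs$truth) && !file.exists(cfg$inputs$truth))
      stop("missing input: truth file '", cfg$inputs$truth,
           "' does not exist")
  }
  invisible(cfg)
}

#' Run the full MoA-prediction pipeline
#'
#' Executes the stages simulate (optional) -> split -> train -> embed GP ->
#' connectivity -> pathway enrichment -> evaluate, writing every stage
#' output under `out_dir` in the package's file dialects, plus a
#' `manifest.json` recording the configuration snapshot, per-stage seeds
#' and output file digests.  All stages are deterministic given the seed;
#' rerunning with the same configuration reproduces every result table
#' byte for byte.
#'
#' @param config a config list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created; existing result files are
#'   overwritten).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fitted model, result tables and the
#'   manifest.
#' @examples
#' \donttest{
#' cfg <- default_pipeline_config(seed = 7)
#' cfg$simulate <- list(n_compounds = 30, n_genes = 10, n_pathways = 2,
#'                      sig_dim = 60, n_bits = 128,
#'                      motif_bits_per_target = 8)
#' cfg$train$max_epochs <- 3
#' cfg$enrichment$n_perm <- 50
#' res <- run_pipeline(cfg, file.path(tempdir(), "demo"))
#' }
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config(config$seed %||% 7L)
  cfg <- utils::modifyList(base, config)
  .check_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  say <- function(...) if (verbose) message("[moable] ", ...)

  # --- stage 1: corpus -------------------------------------------------
  if (is.null(cfg$inputs)) {
    say("simulate: generating synthetic corpus (seed ", seed + 1L, ")")
    sim_args <- utils::modifyList(list(seed = seed + 1L),
                                  cfg$simulate %||% list())
    corpus <- simulate_corpus(do.call(sim_config, sim_args))
    corpus_to_files(corpus, file.path(out_dir, "corpus"))
    fps <- corpus$fingerprints
    csig <- corpus$compound_signatures
    gp <- corpus$gp_signatures
    pathways <- corpus$pathways
    truth <- corpus$truth
    decoys <- corpus$compounds$compound_id[corpus$compounds$is_decoy]
  } else {
    say("load: reading corpus files")
    fps <- read_fingerprints(cfg$inputs$fingerprints)
    csig <- read_signature_gct(cfg$inputs$compound_signatures)
    gp <- read_signature_gct(cfg$inputs$gp_signatures)
    pathways <- read_gmt(cfg$inputs$pathways)
    truth <- if (!is.null(cfg$inputs$truth))
      read_moa_truth(cfg$inputs$truth) else NULL
    decoys <- character(0)
  }

  # --- stage 2: compound-disjoint split --------------------------------
  split <- split_compounds(rownames(fps), cfg$split$fractions,
                           seed = seed + 2L)
  say("split: ", length(split$train), "/", length(split$validation), "/",
      length(split$test), " compounds (train/val/test)")

  # --- stage 3: train the coembedding ----------------------------------
  keep <- csig$column_meta$perturbagen_id %in%
    c(split$train, split$validation)
  train_sig <- subset_samples(csig, csig$column_meta$sample_id[keep])
  say("train: ", sum(keep), " anchor signatures")
  model <- do.call(moable, c(
    list(fingerprints = fps, signatures = train_sig,
         validation = split$validation, seed = seed + 3L,
         verbose = verbose),
    cfg$train))
  write_moable(model, file.path(out_dir, "model"))

  # --- stage 4: GP embedding bank --------------------------------------
  bank <- embed_gp_signatures(model, gp)
  write_embedding_bank(bank, file.path(out_dir, "gp_embeddings.tsv"))

  # --- stage 5: connectivity profiles ----------------------------------
  say("connect: ", nrow(fps), " compounds x ",
      length(unique(bank$meta$target_gene)), " genes")
  Zc <- predict(model, fps, type = "structure")
  profiles <- connectivity_profiles(Zc, bank)
  write_connectivity_tsv(profiles, file.path(out_dir, "profiles.tsv"))

  # --- stage 6: pathway enrichment -------------------------------------
  en <- cfg$enrichment
  say("predict-moa: ", length(pathways), " pathways, ", en$n_perm,
      " permutations (seed ", seed + 4L, ")")
  moa <- predict_moa(profiles, pathways, fdr_threshold = en$fdr_threshold,
                     positive_only = FALSE, n_perm = en$n_perm,
                     weight_p = en$weight_p, seed = seed + 4L,
                     min_size = en$min_size, max_size = en$max_size)
  write_result_tsv(moa, file.path(out_dir, "moa.tsv"))

  # --- stage 7: evaluation ---------------------------------------------
  report <- NULL
  if (!is.null(truth) && length(truth)) {
    say("evaluate: ", length(truth), " labelled compounds")
    report_dir <- file.path(out_dir, "report")
    dir.create(report_dir, showWarnings = FALSE)
    pv <- true_pathway_pvalues(moa, truth)
    auc <- fdr_threshold_auroc(moa, truth)
    report <- eval_report(pv, auc, stratum = "all")
    write_result_tsv(pv, file.path(report_dir, "true_pathway_pvalues.tsv"))
    write_result_tsv(auc, file.path(report_dir, "per_compound_auroc.tsv"))
    writeLines(jsonlite::toJSON(list(
      stratum = report$stratum, median_p = report$median_p,
      median_auroc = report$median_auroc,
      n_compounds = report$n_compounds,
      n_not_evaluable = report$n_not_evaluable),
      auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA),
      file.path(report_dir, "summary.json"))
  }

  manifest <- list(
    command = "run_pipeline",
    config = cfg,
    seeds = list(global = seed, simulate = seed + 1L, split = seed + 2L,
                 train = seed + 3L, enrichment = seed + 4L),
    outputs = as.list(tools::md5sum(list.files(out_dir, recursive = TRUE,
                                               full.names = TRUE,
                                               pattern = "\\.(tsv|gct|gmt)$"))),
    timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(list(model = model, profiles = profiles, moa = moa,
                 report = report, split = split, decoys = decoys,
                 manifest = manifest, out_dir = out_dir))
}

#' End-to-end demonstration on a generated corpus
#'
#' Runs [run_pipeline()] with [default_pipeline_config()] on the default
#' synthetic corpus (200 compounds, 30 perturbed genes, 6 pathways).
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return As [run_pipeline()], invisibly.
#' @export
moable_demo <- function(seed = 7L, out_dir = file.path(tempdir(), "moable_demo"),
                        verbose = TRUE) {
  run_pipeline(default_pipeline_config(seed), out_dir, verbose = verbose)
}

# result tables are written with a fixed numeric format so reruns are
# byte-identical
write_result_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf(.num_fmt, x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
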