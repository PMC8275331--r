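# Shared fixtures.  The end-to-end study fixture (full default corpus,
# trained model, MoA table) is expensive, so it is built lazily once per
# test run and cached for every test that needs it.

.fixture_env <- new.env(parent = emptyenv())

# a small corpus for fast unit tests
tiny_corpus <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_compounds = 30, n_genes = 10, n_pathways = 2,
         genes_per_pathway = 5, n_bits = 128, sig_dim = 60,
         motif_bits_per_target = 8, seed = seed),
    list(...))
  simulate_corpus(do.call(sim_config, args))
}

# a small trained model on a tiny corpus (seconds, not minutes)
tiny_model <- function(corpus, seed = 4, ...) {
  sp <- split_compounds(rownames(corpus$fingerprints), seed = seed)
  cm <- corpus$compound_signatures$column_meta
  keep <- cm$perturbagen_id %in% c(sp$train, sp$validation)
  sig <- subset_samples(corpus$compound_signatures, cm$sample_id[keep])
  args <- utils::modifyList(
    list(fingerprints = corpus$fingerprints, signatures = sig,
         validation = sp$validation, hidden_str = c(64, 32),
         hidden_sig = c(64, 32), output_dim = 32, margin = 1,
         learning_rate = 3e-3, batch_size = 32, max_epochs = 20,
         patience = 8, seed = seed + 1),
    list(...))
  do.call(moable, args)
}

# full default-configuration pipeline run (the study conditions: 200
# compounds, 30 perturbed genes, 6 pathways, 3 GP replicates per gene)
e2e_fixture <- function() {
  if (!is.null(.fixture_env$e2e)) return(.fixture_env$e2e)
  out_dir <- file.path(tempdir(), "moable_e2e_fixture")
  res <- run_pipeline(default_pipeline_config(seed = 1L), out_dir)
  corpus <- corpus_from_files(file.path(out_dir, "corpus"))
  .fixture_env$e2e <- list(res = res, corpus = corpus, out_dir = out_dir)
  .fixture_env$e2e
}

# raw-signature connectivity profiles of the fixture's non-decoy compounds
# (query = the compound's mean replicate signature), cached as well
e2e_raw_profiles <- function() {
  if (!is.null(.fixture_env$raw_profiles)) return(.fixture_env$raw_profiles)
  fx <- e2e_fixture()
  cs <- fx$corpus$compound_signatures
  ids <- names(fx$corpus$truth)
  prof <- lapply(ids, function(cid) {
    cols <- cs$column_meta$sample_id[cs$column_meta$perturbagen_id == cid]
    raw_signature_connectivity(rowMeans(cs$values[, cols, drop = FALSE]),
                               fx$corpus$gp_signatures, cid)
  })
  names(prof) <- ids
  .fixture_env$raw_profiles <- prof
  prof
}

# planted-pathway recovery: among positively enriched candidate pathways,
# does the pathway of the compound's target gene attain the lowest p-value?
planted_recovery <- function(moa, truth) {
  vapply(names(truth), function(cid) {
    sub <- moa[moa$compound_id == cid & moa$ES > 0, , drop = FALSE]
    tp <- truth[[cid]]
    if (!tp %in% sub$pathway_id) return(FALSE)
    sub$p_value[match(tp, sub$pathway_id)] <= min(sub$p_value)
  }, TRUE)
}
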