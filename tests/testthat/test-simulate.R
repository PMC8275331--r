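test_that("generated corpora satisfy their structural invariants", {
  co <- simulate_corpus(sim_config(n_compounds = 60, n_genes = 30,
                                   n_pathways = 6, n_bits = 512,
                                   sig_dim = 120, motif_bits_per_target = 12,
                                   seed = 1))
  expect_s3_class(co, "sim_corpus")
  expect_silent(validate_sim_corpus(co))
  act <- co$compounds[!co$compounds$is_decoy, ]
  gp_meta <- co$gp_signatures$column_meta
  expect_true(all(act$target_gene %in% gp_meta$target_gene))
  expect_true(all(act$target_gene %in% unlist(co$pathways)))
  expect_true(all(gp_meta$pert_type != "compound"))
  expect_true(all(nchar(gp_meta$target_gene) > 0))
  # determinism
  co2 <- simulate_corpus(sim_config(n_compounds = 60, n_genes = 30,
                                    n_pathways = 6, n_bits = 512,
                                    sig_dim = 120,
                                    motif_bits_per_target = 12, seed = 1))
  expect_identical(co$fingerprints, co2$fingerprints)
  expect_identical(co$compound_signatures$values,
                   co2$compound_signatures$values)
})

test_that("the noiseless limit plants an exact linkage", {
  co <- tiny_corpus(seed = 31, structure_noise_rate = 0,
                    signature_noise_sd = 0, decoy_compound_fraction = 0)
  tm <- co$target_map
  shared <- outer(tm, tm, `==`)
  cs <- co$compound_signatures
  first_rep <- function(cid)
    cs$values[, which(cs$column_meta$perturbagen_id == cid)[1]]
  for (i in seq_along(tm)) {
    for (j in seq_len(i - 1)) {
      if (shared[i, j]) {
        # same target: identical signatures
        expect_identical(first_rep(names(tm)[i]), first_rep(names(tm)[j]))
      }
    }
  }
  # each compound's signature is most similar to its own target's GP column
  gp <- co$gp_signatures
  for (cid in names(tm)) {
    p <- raw_signature_connectivity(first_rep(cid), gp, cid)
    expect_identical(p$gene[which.max(p$score)], unname(tm[cid]))
    expect_equal(max(p$score), 1)
  }
})

test_that("noiseless same-target compounds share their motif bits", {
  co <- tiny_corpus(seed = 32, structure_noise_rate = 0,
                    base_bit_rate = 0, decoy_compound_fraction = 0)
  # with no background and no flips, fingerprints are exactly the motif
  tm <- co$target_map
  for (g in unique(tm)) {
    ids <- names(tm)[tm == g]
    if (length(ids) < 2) next
    for (k in seq(2, length(ids)))
      expect_identical(co$fingerprints[ids[1], ], co$fingerprints[ids[k], ])
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_genes = 4, n_pathways = 6), "as many genes")
  expect_error(sim_config(n_bits = 64, n_genes = 30,
                          motif_bits_per_target = 32), "motif bit demand")
  expect_error(sim_config(structure_noise_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 40, sig_dim = 30, n_pathways = 4,
                          genes_per_pathway = 5, n_bits = 2048),
               "sig_dim")
})

test_that("corpus files round-trip through the I/O dialects", {
  co <- tiny_corpus(seed = 33)
  dir <- withr::local_tempdir()
  corpus_to_files(co, dir)
  expect_identical(length(readLines(file.path(dir, "pathways.gmt"))),
                   length(co$pathways))
  gct <- read_signature_gct(file.path(dir, "compound_signatures.gct"))
  expect_identical(ncol(gct$values),
                   co$config$n_compounds * co$config$n_sig_per_compound)
  back <- corpus_from_files(dir)
  expect_identical(back$fingerprints, co$fingerprints)
  expect_equal(back$compound_signatures$values,
               co$compound_signatures$values, tolerance = 1e-9)
  expect_equal(back$gp_signatures$values, co$gp_signatures$values,
               tolerance = 1e-9)
  expect_identical(back$compound_signatures$column_meta,
                   co$compound_signatures$column_meta)
  expect_identical(back$truth, co$truth)
  expect_identical(unclass(back$pathways)[seq_along(co$pathways)],
                   unclass(co$pathways)[seq_along(co$pathways)])
})

test_that("planted-linkage recovery degrades monotonically with structure noise", {
  recov <- function(noise, seed) {
    cfg <- sim_config(n_compounds = 45, n_genes = 10, n_pathways = 2,
                      genes_per_pathway = 5, n_bits = 256, sig_dim = 80,
                      motif_bits_per_target = 12,
                      structure_noise_rate = noise,
                      decoy_compound_fraction = 0, seed = seed)
    co <- simulate_corpus(cfg)
    m <- tiny_model(co, seed = seed + 1, batch_size = 64,
                    learning_rate = 3e-3, max_epochs = 40, patience = 10)
    bank <- embed_gp_signatures(m, co$gp_signatures)
    pr <- connectivity_profiles(predict(m, co$fingerprints,
                                        type = "structure"), bank)
    mean(vapply(names(co$target_map), function(cid) {
      p <- pr[[cid]]
      rank(-p$score)[match(co$target_map[cid], p$gene)] <= 3
    }, TRUE))
  }
  rates <- vapply(c(0, 0.2, 0.4), function(nz)
    mean(vapply(1:3, function(s) recov(nz, s), numeric(1))), numeric(1))
  expect_gte(rates[1], rates[2])
  expect_gte(rates[2], rates[3])
})
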