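make_net <- function(seed = 1, input = 40, hidden = c(16, 8), out = 8)
  moable:::with_seed(seed, moable:::mlp_init(input, c(hidden, out)))

test_that("encoder forward pass has the right shape and batches consistently", {
  net <- make_net()
  X <- matrix(rnorm(5 * 40), 5, 40)
  Z <- moable:::mlp_forward(net, X)
  expect_identical(dim(Z), c(5L, 8L))
  one_by_one <- t(vapply(1:5, function(i)
    drop(moable:::mlp_forward(net, X[i, , drop = FALSE])), numeric(8)))
  expect_equal(Z, one_by_one, tolerance = 1e-12)
  expect_error(moable:::mlp_forward(net, matrix(0, 2, 17)), "expects 40")
})

test_that("backpropagation matches numerical gradients", {
  net <- make_net(seed = 2, input = 7, hidden = c(5), out = 3)
  X <- matrix(rnorm(4 * 7), 4, 7)
  # scalar loss: sum of squares of the output
  fwd <- moable:::mlp_forward(net, X, keep_cache = TRUE)
  grads <- moable:::mlp_backward(net, fwd, 2 * fwd$out)
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in list(c(1, 1), c(3, 2))) {
      plus <- net; plus$layers[[l]]$W[idx[1], idx[2]] <-
        plus$layers[[l]]$W[idx[1], idx[2]] + eps
      minus <- net; minus$layers[[l]]$W[idx[1], idx[2]] <-
        minus$layers[[l]]$W[idx[1], idx[2]] - eps
      num <- (sum(moable:::mlp_forward(plus, X)^2) -
                sum(moable:::mlp_forward(minus, X)^2)) / (2 * eps)
      expect_equal(grads[[l]]$W[idx[1], idx[2]], num, tolerance = 1e-5)
    }
  }
})

test_that("training reduces the validation loss on a learnable corpus", {
  co <- tiny_corpus(seed = 21, n_compounds = 50)
  m <- tiny_model(co, seed = 5)
  expect_lt(tail(m$log$val_loss, 1), m$log$val_loss[1])
})

test_that("fits are bitwise reproducible given the seed", {
  co <- tiny_corpus(seed = 22)
  m1 <- tiny_model(co, seed = 6, max_epochs = 6)
  m2 <- tiny_model(co, seed = 6, max_epochs = 6)
  expect_identical(m1$str_net, m2$str_net)
  expect_identical(m1$sig_net, m2$sig_net)
  expect_identical(m1$log, m2$log)
  m3 <- tiny_model(co, seed = 7, max_epochs = 6)
  expect_false(identical(m1$str_net, m3$str_net))
})

test_that("inference is deterministic and respects provenance", {
  co <- tiny_corpus(seed = 23)
  m <- tiny_model(co, seed = 8, max_epochs = 5)
  Z1 <- predict(m, co$fingerprints, type = "structure")
  Z2 <- predict(m, co$fingerprints, type = "structure")
  expect_identical(Z1, Z2)
  expect_identical(dim(Z1), c(30L, 32L))
  expect_identical(dim(predict(m, matrix(0.5, 0, 60),
                               type = "signature")), c(0L, 32L))
  bank <- embed_gp_signatures(m, co$gp_signatures)
  expect_identical(nrow(bank$vectors),
                   ncol(co$gp_signatures$values))
  expect_true(all(bank$meta$provenance == "gp_signature"))
  # definitional: bank rows equal the signature encoder applied per column
  direct <- predict(m, co$gp_signatures, type = "signature")
  expect_equal(unname(bank$vectors), unname(direct), tolerance = 1e-12)
})

test_that("after training, anchors sit closer to their own structure than to others", {
  # one compound per gene, noiseless signatures: the margin must be realized
  cfg <- sim_config(n_compounds = 20, n_genes = 20, n_pathways = 4,
                    genes_per_pathway = 5, n_bits = 256, sig_dim = 80,
                    motif_bits_per_target = 10, structure_noise_rate = 0,
                    signature_noise_sd = 0, decoy_compound_fraction = 0,
                    n_sig_per_compound = 2, seed = 11)
  co <- simulate_corpus(cfg)
  m <- moable(co$fingerprints, co$compound_signatures, validation = NULL,
              hidden_str = c(64, 32), hidden_sig = c(64, 32),
              output_dim = 32, margin = 0.2, learning_rate = 3e-3,
              batch_size = 40, max_epochs = 60, seed = 3)
  Zs <- predict(m, co$compound_signatures, type = "signature")
  Zc <- predict(m, co$fingerprints, type = "structure")
  S <- cosine_matrix(Zs, Zc)
  own <- match(co$compound_signatures$column_meta$perturbagen_id,
               rownames(Zc))
  pos <- S[cbind(seq_len(nrow(S)), own)]
  neg <- (rowSums(S) - pos) / (ncol(S) - 1)
  expect_gte(mean(pos) - mean(neg), m$config$margin)
})

test_that("model archives and embedding banks round-trip", {
  co <- tiny_corpus(seed = 24)
  m <- tiny_model(co, seed = 9, max_epochs = 5)
  dir <- withr::local_tempdir()
  write_moable(m, dir)
  m2 <- read_moable(dir)
  expect_identical(m2$str_net, m$str_net)
  expect_equal(predict(m2, co$fingerprints, type = "structure"),
               predict(m, co$fingerprints, type = "structure"))
  bank <- embed_gp_signatures(m, co$gp_signatures)
  path <- file.path(dir, "bank.tsv")
  write_embedding_bank(bank, path)
  back <- read_embedding_bank(path)
  expect_identical(back$meta, bank$meta)
  expect_equal(back$vectors, bank$vectors, tolerance = 1e-9)
  # byte stability at the documented precision
  path2 <- file.path(dir, "bank2.tsv")
  write_embedding_bank(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degenerate training inputs are rejected", {
  co <- tiny_corpus(seed = 25)
  one <- subset_samples(co$compound_signatures,
                        co$compound_signatures$column_meta$sample_id[1:3])
  expect_error(moable(co$fingerprints, one, hidden_str = c(8),
                      hidden_sig = c(8), output_dim = 4),
               "2 distinct compounds")
  expect_error(moable(co$fingerprints, co$gp_signatures),
               "compound columns only")
})
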