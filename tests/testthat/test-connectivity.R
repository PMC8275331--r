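test_that("gene connectivity is the max cosine over replicates", {
  q <- c(1, 0, 0)
  reps <- rbind(c(0.2, 1, 0), c(1, 0.2, 0), c(-1, 0.5, 0))
  sims <- apply(reps, 1, cosine_similarity, u = q)
  expect_equal(gene_connectivity(q, reps), max(sims))
  # single replicate degenerates to plain cosine similarity
  expect_equal(gene_connectivity(q, reps[1, , drop = FALSE]), sims[1])
  # brute force over many random replicates
  set.seed(14)
  for (i in 1:10) {
    q <- rnorm(12)
    reps <- matrix(rnorm(50 * 12), 50, 12)
    expect_equal(gene_connectivity(q, reps),
                 max(vapply(1:50, function(j)
                   cosine_similarity(q, reps[j, ]), numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("adding a replicate never decreases a gene's connectivity", {
  set.seed(15)
  for (i in 1:20) {
    q <- rnorm(8)
    reps <- matrix(rnorm(5 * 8), 5, 8)
    extra <- rbind(reps, rnorm(8))
    expect_gte(gene_connectivity(q, extra), gene_connectivity(q, reps))
  }
})

random_bank <- function(n_genes = 6, reps = 3, d = 10, seed = 16) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * reps * d), n_genes * reps, d)
  rownames(v) <- sprintf("s%02d", seq_len(nrow(v)))
  embedding_bank(v, "gp_signature",
                 target_gene = rep(sprintf("G%02d", seq_len(n_genes)),
                                   each = reps),
                 pert_type = rep(c("knock-down", "knock-out",
                                   "over-expression"), length.out = nrow(v)))
}

test_that("profiles have one bounded score per distinct gene, order-free", {
  bank <- random_bank()
  q <- rnorm(10)
  p <- connectivity_profile(q, bank, "cmpd")
  expect_identical(nrow(p), 6L)
  expect_setequal(p$gene, unique(bank$meta$target_gene))
  expect_true(all(p$score >= -1 & p$score <= 1))
  # permuting the bank entries changes nothing
  perm <- sample(nrow(bank$vectors))
  bank2 <- embedding_bank(bank$vectors[perm, ], "gp_signature",
                          target_gene = bank$meta$target_gene[perm],
                          pert_type = bank$meta$pert_type[perm])
  expect_equal(connectivity_profile(q, bank2, "cmpd")$score, p$score)
  # profile equals gene-wise gene_connectivity calls
  gene_wise <- vapply(sort(unique(bank$meta$target_gene)), function(g)
    gene_connectivity(q, bank$vectors[bank$meta$target_gene == g, ,
                                      drop = FALSE]), numeric(1))
  expect_equal(p$score, unname(gene_wise))
})

test_that("raw mode shares the core algorithm with embedding mode", {
  co <- tiny_corpus(seed = 26)
  gp <- co$gp_signatures
  # identity "encoder": a bank holding the raw GP columns themselves
  bank <- embedding_bank(t(gp$values), "gp_signature",
                         target_gene = gp$column_meta$target_gene,
                         pert_type = gp$column_meta$pert_type)
  q <- rnorm(nrow(gp$values))
  emb <- connectivity_profile(q, bank, "x")
  raw <- raw_signature_connectivity(q, gp, "x")
  expect_equal(emb$score, raw$score)
  expect_identical(emb$gene, raw$gene)
  expect_identical(attr(raw, "mode"), "raw_signature")
  # a compound signature equal to one GP column scores 1 for that gene
  g1 <- gp$column_meta$target_gene[1]
  self <- raw_signature_connectivity(gp$values[, 1], gp, "self")
  expect_equal(self$score[match(g1, self$gene)], 1)
})

test_that("raw-mode scores match hand-computed cosine maxima", {
  co <- tiny_corpus(seed = 27, n_genes = 5, n_pathways = 1)
  gp <- co$gp_signatures
  set.seed(18)
  q <- rnorm(nrow(gp$values))
  p <- raw_signature_connectivity(q, gp, "x")
  for (g in p$gene) {
    cols <- which(gp$column_meta$target_gene == g)
    by_hand <- max(vapply(cols, function(j)
      sum(q * gp$values[, j]) /
        sqrt(sum(q^2) * sum(gp$values[, j]^2)), numeric(1)))
    expect_equal(p$score[match(g, p$gene)], by_hand, tolerance = 1e-12)
  }
})
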