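test_that("enrichment score handles the degenerate textbook cases", {
  ranked <- data.frame(gene = c("g1", "g2"), score = c(1, 0.5))
  expect_equal(enrichment_score(ranked, "g1", weight_p = 0)$ES, 1)
  # set covering the whole list: running sum peaks at 1 after the last hit
  expect_equal(enrichment_score(ranked, c("g1", "g2"), weight_p = 0)$ES, 1)
  expect_error(enrichment_score(ranked, "absent"), "no overlap")
})

test_that("ranking is deterministic with ties broken by gene id", {
  r <- rank_genes(c(b = 1, a = 1, c = 2))
  expect_identical(r$gene, c("c", "a", "b"))
  expect_error(rank_genes(c(a = 1, a = 2)), "duplicate")
})

test_that("enrichment score matches the step-by-step oracle and fgsea", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(12:50, 1)
    scores <- stats::setNames(rnorm(n), sprintf("g%03d", seq_len(n)))
    ranked <- rank_genes(scores)
    gs <- sample(ranked$gene, sample(2:10, 1))
    for (p in c(0, 1)) {
      oracle <- oracle_es(ranked$gene, ranked$score, gs, p)
      if (oracle$tied) next   # the sign of the statistic is conventional
      es <- enrichment_score(ranked, gs, weight_p = p)$ES
      expect_equal(es, oracle$ES, tolerance = 1e-9)
      if (p == 0)
        expect_equal(es, oracle_ks(ranked$gene, gs), tolerance = 1e-9)
    }
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    stats_vec <- stats::setNames(sort(rnorm(n), decreasing = TRUE),
                                 sprintf("g%03d", seq_len(n)))
    hit <- sort(sample(n, sample(3:8, 1)))
    oracle <- oracle_es(names(stats_vec), unname(stats_vec),
                        names(stats_vec)[hit], 1)
    if (oracle$tied) next
    es <- enrichment_score(data.frame(gene = names(stats_vec),
                                      score = unname(stats_vec)),
                           names(stats_vec)[hit], weight_p = 1)$ES
    expect_equal(es, fgsea::calcGseaStat(stats_vec, hit, gseaParam = 1),
                 tolerance = 1e-9)
  }
})

test_that("reversing the ranked list negates the unweighted score", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    ranked <- rank_genes(stats::setNames(rnorm(n),
                                         sprintf("g%03d", seq_len(n))))
    gs <- sample(ranked$gene, sample(2:6, 1))
    fwd <- enrichment_score(ranked, gs, weight_p = 0)
    rev_ranked <- ranked[rev(seq_len(n)), ]
    bwd <- enrichment_score(rev_ranked, gs, weight_p = 0)
    expect_equal(abs(bwd$ES), abs(fwd$ES), tolerance = 1e-12)
    # signed symmetry holds whenever the extreme deviation is unique in size
    if (abs(max(fwd$running_sum) + min(fwd$running_sum)) > 1e-9)
      expect_equal(bwd$ES, -fwd$ES, tolerance = 1e-12)
  }
})

test_that("permutation p-values are smoothed, bounded and reproducible", {
  set.seed(44)
  scores <- stats::setNames(rnorm(40), sprintf("g%02d", 1:40))
  pc <- pathway_collection(list(A = sprintf("g%02d", 1:8),
                                B = sprintf("g%02d", 20:27),
                                C = sprintf("g%02d", c(1, 5, 9, 33, 40))))
  r1 <- gsea_preranked(scores, pc, n_perm = 10, seed = 7)
  r2 <- gsea_preranked(scores, pc, n_perm = 10, seed = 7)
  expect_identical(r1, r2)                    # bitwise determinism
  expect_true(all(r1$p_value >= 1 / 11))
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_true(all(abs(r1$ES) <= 1))
  expect_true(all(r1$FDR >= 0 & r1$FDR <= 1))
  # input order of pathways is irrelevant
  r3 <- gsea_preranked(scores, pc[c(3, 1, 2)], n_perm = 10, seed = 7)
  expect_identical(r1, r3)
})

test_that("pathways outside the size bounds are excluded with reasons", {
  scores <- stats::setNames(rnorm(30), sprintf("g%02d", 1:30))
  pc <- pathway_collection(list(small = c("g01", "g02"),
                                none = c("zz1", "zz2", "zz3", "zz4", "zz5"),
                                ok = sprintf("g%02d", 3:9)))
  r <- gsea_preranked(scores, pc, n_perm = 20, seed = 1, min_size = 5)
  expect_identical(r$pathway_id, "ok")
  sk <- attr(r, "skipped")
  expect_setequal(sk$pathway_id, c("small", "none"))
  expect_match(sk$reason[sk$pathway_id == "none"], "no overlap")
})

test_that("direct-signature enrichment is the preranked test on sorted values", {
  set.seed(45)
  sig <- stats::setNames(rnorm(50), sprintf("g%02d", 1:50))
  pc <- pathway_collection(list(A = sprintf("g%02d", 1:8),
                                B = sprintf("g%02d", 30:37)))
  direct <- direct_signature_enrichment(sig, pc, n_perm = 50, seed = 3)
  pre <- gsea_preranked(rank_genes(sig), pc, n_perm = 50, seed = 3)
  expect_identical(direct, pre)
  expect_error(direct_signature_enrichment(unname(sig), pc), "gene ids")
  # a pathway occupying the top of the signature maximizes the score
  sig2 <- sig
  sig2[pc$B] <- sig2[pc$B] + 10
  r2 <- direct_signature_enrichment(sig2, pc, n_perm = 50, seed = 3)
  expect_identical(r2$pathway_id[which.max(r2$ES)], "B")
})

test_that("MoA calling flags positively enriched pathways under the FDR cut", {
  co <- tiny_corpus(seed = 28)
  bank <- embedding_bank(t(co$gp_signatures$values), "gp_signature",
                         target_gene = co$gp_signatures$column_meta$target_gene,
                         pert_type = co$gp_signatures$column_meta$pert_type)
  cs <- co$compound_signatures
  cid <- names(co$truth)[1]
  cols <- cs$column_meta$sample_id[cs$column_meta$perturbagen_id == cid]
  prof <- connectivity_profile(rowMeans(cs$values[, cols, drop = FALSE]),
                               bank, cid)
  moa <- predict_moa(prof, co$pathways, n_perm = 200, seed = 5)
  expect_true(all(moa$ES >= 0))
  expect_identical(moa$significant, moa$FDR < 0.1)
  full <- predict_moa(prof, co$pathways, n_perm = 200, seed = 5,
                      positive_only = FALSE)
  expect_gte(nrow(full), nrow(moa))
})
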