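# Independent oracles used by the tests.  These are deliberately coded in a
# different style from the package internals (explicit loops, ecdf algebra)
# so they constitute independent checks, not re-expressions of the same
# code.

# step-by-step weighted running-sum enrichment score; also reports whether
# the extreme deviation is an exact positive/negative tie (where the sign
# of the statistic is a tie-break convention, not a numerical property)
oracle_es <- function(ranked_genes, ranked_scores, gene_set, p) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  nr <- sum(abs(ranked_scores[hit])^p)
  n_miss <- n - sum(hit)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + abs(ranked_scores[i])^p / nr
           else cur - 1 / n_miss
    run[i] <- cur
  }
  list(ES = run[which.max(abs(run))],
       tied = abs(max(run) + min(run)) < 1e-9)
}

# classic unweighted Kolmogorov-Smirnov statistic as the signed supremum of
# the difference between the hit and miss empirical distribution functions
oracle_ks <- function(ranked_genes, gene_set) {
  hit <- ranked_genes %in% gene_set
  d <- cumsum(hit) / sum(hit) - cumsum(!hit) / sum(!hit)
  d[which.max(abs(d))]
}

# AUROC as the fraction of correctly ordered (positive, negative) pairs,
# ties counting one half
oracle_auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
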