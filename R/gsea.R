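#' Rank genes by score
#'
#' Produces the ranked gene list consumed by the preranked enrichment test:
#' sorted by score descending, ties broken by gene id ascending so the
#' ranking is fully deterministic.
#'
#' @param scores named numeric vector (names = gene ids, no duplicates).
#' @return data.frame with columns `gene`, `score`, sorted.
#' @export
rank_genes <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("'scores' must be a named vector of gene scores")
  if (anyDuplicated(names(scores)))
    stop("duplicate gene ids in scores: ",
         paste(unique(names(scores)[duplicated(names(scores))]), collapse = ", "))
  if (!all(is.finite(scores))) stop("gene scores must be finite")
  ord <- order(-scores, names(scores))
  data.frame(gene = names(scores)[ord], score = unname(scores)[ord],
             stringsAsFactors = FALSE)
}

# running-sum core on a ranked weight vector: hits step up by their
# normalized weight |s|^p, misses step down by 1/(n - k).  ES is the signed
# maximum deviation from zero (first index on the rare exact tie).
.es_core <- function(w, hit_idx) {
  n <- length(w)
  k <- length(hit_idx)
  wh <- w[hit_idx]
  tot <- sum(wh)
  step <- if (k == n) numeric(n) else rep.int(-1 / (n - k), n)
  step[hit_idx] <- if (tot == 0) 1 / k else wh / tot
  run <- cumsum(step)
  list(ES = run[which.max(abs(run))], running_sum = run)
}

#' Weighted running-sum enrichment score
#'
#' The Kolmogorov-Smirnov-style enrichment statistic on a ranked gene list:
#' walking down the ranking, the running sum rises by `|score|^p`
#' (normalized over the in-set hits) at each gene of the set and falls by
#' `1/(n - k)` at each miss; the enrichment score is the signed maximum
#' deviation of this running sum from zero.  With `weight_p = 0` this is the
#' classic unweighted Kolmogorov-Smirnov statistic.
#'
#' @param ranked a ranked gene list from [rank_genes()] (or any data.frame
#'   with `gene` and `score` in ranked order).
#' @param gene_set character vector of gene symbols.
#' @param weight_p non-negative rank weight exponent (default 1).
#' @return List with elements `ES` (in `[-1, 1]`) and `running_sum` (length
#'   = number of ranked genes).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(is.data.frame(ranked), nrow(ranked) >= 1, weight_p >= 0)
  hit_idx <- which(ranked$gene %in% gene_set)
  if (length(hit_idx) == 0)
    stop("gene set has no overlap with the ranked list (not evaluable)")
  .es_core(abs(ranked$score)^weight_p, hit_idx)
}

# null ES values for a set of size k on the fixed ranked weights:
# set membership reassigned uniformly at random to positions, scores fixed.
.null_es <- function(w, k, n_perm) {
  n <- length(w)
  vapply(seq_len(n_perm),
         function(b) .es_core(w, sample.int(n, k))$ES,
         numeric(1))
}

#' Preranked gene set enrichment with a gene-permutation null
#'
#' For every pathway with an overlap of `min_size`..`max_size` genes with
#' the ranked list, computes the weighted enrichment score, a permutation
#' null (set membership reassigned uniformly at random to ranked positions,
#' scores fixed; nulls are shared across pathways of equal overlap size
#' since they depend only on the size), a sign-stratified nominal p-value
#' with add-one smoothing, the normalized enrichment score, and the
#' ratio-of-tails false discovery rate.
#'
#' The nominal p-value is
#' `(1 + # same-sign nulls as or more extreme) / (1 + # same-sign nulls)`;
#' it is never 0 and never below `1/(n_perm + 1)`, so significance calls at
#' a fixed FDR threshold are reproducible at finite `n_perm`.  NES is
#' `ES / mean(|null ES| of the same sign)`.  The FDR of a pathway is the
#' fraction of pooled same-sign null NES values at least as extreme as its
#' NES divided by the corresponding fraction of observed NES values, made
#' monotone in |NES| and capped at 1.
#'
#' @param scores named numeric vector of per-gene scores (e.g. connectivity
#'   scores), or a ranked data.frame from [rank_genes()].
#' @param pathways a `pathway_collection` (see [read_gmt()]).
#' @param n_perm number of permutations (default 1000).
#' @param weight_p rank weight exponent (default 1).
#' @param seed integer seed; results are bitwise reproducible.
#' @param min_size,max_size overlap-size bounds (defaults 5 and 500);
#'   pathways outside the bounds, or with no overlap, are excluded and
#'   listed in the `skipped` attribute.
#' @return data.frame (one row per retained pathway, sorted by pathway id)
#'   with columns `pathway_id`, `ES`, `NES`, `p_value`, `FDR`, `n_overlap`;
#'   attribute `skipped` is a data.frame of excluded pathways and reasons.
#' @export
gsea_preranked <- function(scores, pathways, n_perm = 1000, weight_p = 1,
                           seed = 1L, min_size = 5, max_size = 500) {
  stopifnot(n_perm >= 1)
  ranked <- if (is.data.frame(scores)) scores else rank_genes(scores)
  ids <- sort(names(pathways))
  overlap <- lapply(pathways, function(gs) which(ranked$gene %in% gs))
  k <- lengths(overlap)[ids]
  reason <- ifelse(k == 0, "no overlap with ranked genes",
                   ifelse(k < min_size, "overlap below min_size",
                          ifelse(k > max_size, "overlap above max_size", "")))
  keep <- ids[reason == ""]
  skipped <- data.frame(pathway_id = ids[reason != ""],
                        reason = reason[reason != ""],
                        stringsAsFactors = FALSE)
  if (!length(keep)) {
    out <- data.frame(pathway_id = character(0), ES = numeric(0),
                      NES = numeric(0), p_value = numeric(0),
                      FDR = numeric(0), n_overlap = integer(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  w <- abs(ranked$score)^weight_p
  es <- vapply(keep, function(id) .es_core(w, overlap[[id]])$ES, numeric(1))
  nulls_by_k <- with_seed(seed, {
    sizes <- sort(unique(k[keep]))
    stats::setNames(lapply(sizes, function(kk) .null_es(w, kk, n_perm)),
                    sizes)
  })
  res <- do.call(rbind, lapply(seq_along(keep), function(i) {
    null <- nulls_by_k[[as.character(k[keep[i]])]]
    e <- es[i]
    if (e >= 0) {
      same <- null[null >= 0]
      p <- (1 + sum(same >= e)) / (1 + length(same))
      nes <- if (length(same) && mean(same) > 0) e / mean(same) else NA_real_
    } else {
      same <- null[null < 0]
      p <- (1 + sum(same <= e)) / (1 + length(same))
      nes <- if (length(same)) e / mean(abs(same)) else NA_real_
    }
    data.frame(pathway_id = keep[i], ES = e, NES = nes, p_value = p,
               n_overlap = k[keep[i]], stringsAsFactors = FALSE)
  }))
  # pooled null NES for the ratio-of-tails FDR
  null_nes <- unlist(lapply(keep, function(id) {
    null <- nulls_by_k[[as.character(k[id])]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }), use.names = FALSE)
  res$FDR <- .fdr_ratio_of_tails(res$NES, null_nes)
  rownames(res) <- NULL
  out <- res[order(res$pathway_id),
             c("pathway_id", "ES", "NES", "p_value", "FDR", "n_overlap")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# sign-stratified ratio-of-tails q-values, monotone in |NES|, capped at 1
.fdr_ratio_of_tails <- function(obs_nes, null_nes) {
  q <- rep(NA_real_, length(obs_nes))
  pos <- which(!is.na(obs_nes) & obs_nes >= 0)
  neg <- which(!is.na(obs_nes) & obs_nes < 0)
  null_pos <- null_nes[null_nes >= 0]
  null_neg <- null_nes[null_nes < 0]
  for (i in pos) {
    num <- if (length(null_pos)) mean(null_pos >= obs_nes[i]) else 0
    den <- mean(obs_nes[pos] >= obs_nes[i])
    q[i] <- min(1, num / den)
  }
  for (i in neg) {
    num <- if (length(null_neg)) mean(null_neg <= obs_nes[i]) else 0
    den <- mean(obs_nes[neg] <= obs_nes[i])
    q[i] <- min(1, num / den)
  }
  # q-value monotonization: the FDR of a pathway is the best (smallest)
  # ratio among rejection thresholds loose enough to call it -- so q is
  # non-increasing in |NES|, running the cummin from least to most extreme
  if (length(pos) > 1) {
    ord <- pos[order(obs_nes[pos])]
    q[ord] <- cummin(q[ord])
  }
  if (length(neg) > 1) {
    ord <- neg[order(-obs_nes[neg])]
    q[ord] <- cummin(q[ord])
  }
  q
}

#' Direct-signature pathway enrichment (TS-978-style baseline)
#'
#' Ranks the signature's genes by their raw expression values (descending)
#' and runs the identical preranked enrichment test -- the baseline differs
#' from the connectivity pipeline only in what is ranked.
#'
#' @param signature named numeric vector: a compound's signature with gene
#'   ids as names.
#' @param pathways a `pathway_collection`.
#' @param ... passed to [gsea_preranked()].
#' @return As [gsea_preranked()].
#' @export
direct_signature_enrichment <- function(signature, pathways, ...) {
  if (is.null(names(signature)))
    stop("'signature' needs gene ids as names")
  gsea_preranked(signature, pathways, ...)
}

#' Predict MoA pathways for connectivity profiles
#'
#' Runs preranked enrichment on each compound's connectivity-ranked genes
#' and flags pathways with `FDR < fdr_threshold` as mechanism-of-action
#' candidates.  MoA candidates are positively enriched pathways; depleted
#' (negative-ES) pathways are dropped unless `positive_only = FALSE`.
#'
#' @param profiles a [connectivity_profile] or list of them.
#' @param pathways a `pathway_collection`.
#' @param fdr_threshold significance cutoff on the FDR (default 0.1).
#' @param positive_only report only positively enriched pathways (default
#'   `TRUE`).
#' @param ... passed to [gsea_preranked()] (`n_perm`, `weight_p`, `seed`,
#'   `min_size`, `max_size`).
#' @return data.frame with columns `compound_id`, `pathway_id`, `ES`,
#'   `NES`, `p_value`, `FDR`, `n_overlap`, `significant`.
#' @export
predict_moa <- function(profiles, pathways, fdr_threshold = 0.1,
                        positive_only = TRUE, ...) {
  if (inherits(profiles, "connectivity_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    res <- gsea_preranked(stats::setNames(p$score, p$gene), pathways, ...)
    if (nrow(res) == 0) return(NULL)
    cbind(data.frame(compound_id = attr(p, "compound_id"),
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, tabs)
  if (is.null(out))
    out <- data.frame(compound_id = character(0), pathway_id = character(0),
                      ES = numeric(0), NES = numeric(0), p_value = numeric(0),
                      FDR = numeric(0), n_overlap = integer(0))
  if (positive_only) out <- out[out$ES >= 0, , drop = FALSE]
  out$significant <- out$FDR < fdr_threshold
  rownames(out) <- NULL
  out
}
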