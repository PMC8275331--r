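#' P-values of true MoA pathways
#'
#' Looks up, for each compound, the enrichment p-values of its true MoA
#' pathways from a `predict_moa`-style result table.  Truth pathways that
#' were not evaluated for a compound (no overlap with the ranked genes, or
#' outside the size bounds) are reported as not evaluable, never silently
#' dropped.
#'
#' @param results data.frame with columns `compound_id`, `pathway_id`,
#'   `p_value` (e.g. from [predict_moa()] with `positive_only = FALSE`).
#' @param truth named list: compound id -> character vector of true pathway
#'   ids (see [read_moa_truth()]).
#' @return data.frame with one row per (compound, true pathway):
#'   `compound_id`, `pathway_id`, `p_value` (NA when not evaluable),
#'   `evaluable`.
#' @export
true_pathway_pvalues <- function(results, truth) {
  missing_c <- setdiff(names(truth), unique(results$compound_id))
  if (length(missing_c))
    stop("compound(s) missing from results: ",
         paste(missing_c, collapse = ", "))
  rows <- lapply(names(truth), function(cid) {
    sub <- results[results$compound_id == cid, , drop = FALSE]
    p <- sub$p_value[match(truth[[cid]], sub$pathway_id)]
    data.frame(compound_id = cid, pathway_id = truth[[cid]],
               p_value = p, evaluable = !is.na(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-compound AUROC over FDR-thresholded pathway calls
#'
#' For each compound, uses the enrichment FDR as the decision score (lower
#' FDR = more confidently called positive) and computes the area under the
#' ROC curve of true-versus-false pathways swept over FDR thresholds.  The
#' area is computed with the rank statistic (Mann-Whitney) using midranks,
#' so ties in FDR contribute 1/2 and a compound whose pathways all share one
#' FDR scores exactly 0.5.  Compounds with no true or no false pathway
#' among the evaluated ones cannot yield an ROC and are excluded with a
#' reason.
#'
#' @param results data.frame with columns `compound_id`, `pathway_id`,
#'   `FDR`.
#' @param truth named list: compound id -> true pathway ids (expanded MoA
#'   labels).
#' @return data.frame `compound_id`, `auroc`, `n_true`, `n_false`;
#'   attribute `excluded` lists one-class compounds.
#' @export
fdr_threshold_auroc <- function(results, truth) {
  rows <- list(); excl <- list()
  for (cid in names(truth)) {
    sub <- results[results$compound_id == cid & !is.na(results$FDR), ,
                   drop = FALSE]
    lab <- sub$pathway_id %in% truth[[cid]]
    if (!any(lab) || all(lab) || nrow(sub) == 0) {
      excl[[cid]] <- data.frame(compound_id = cid,
                                reason = "needs >=1 true and >=1 false pathway",
                                stringsAsFactors = FALSE)
      next
    }
    rows[[cid]] <- data.frame(compound_id = cid,
                              auroc = .rank_auroc(-sub$FDR, lab),
                              n_true = sum(lab), n_false = sum(!lab),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out))
    out <- data.frame(compound_id = character(0), auroc = numeric(0),
                      n_true = integer(0), n_false = integer(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- do.call(rbind, c(excl, list(NULL)))
  out
}

# Mann-Whitney AUROC with midrank tie handling:
# AUC = (mean rank of positives - (n1+1)/2) / n0
.rank_auroc <- function(score, positive) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(positive); n0 <- sum(!positive)
  (mean(r[positive]) - (n1 + 1) / 2) / n0
}

#' Correlation between embedding- and raw-signature connectivity
#'
#' Checks how well connectivity associations are retained in the embedding
#' space: for each compound, the Pearson correlation between its
#' embedding-based per-gene connectivity scores and its raw-signature-based
#' scores over the shared gene universe.  (On the full-scale L1000 corpus
#' this distribution has been reported around mean 0.40, SD 0.09; that
#' magnitude is a reference point for real data, not a test threshold.)
#'
#' @param embedding_profiles,signature_profiles named lists of
#'   [connectivity_profile] objects with matching compound ids.
#' @return List with `per_compound` (data.frame `compound_id`, `r`,
#'   `n_genes`) and `summary` (mean, sd, n).
#' @export
embedding_fidelity_correlation <- function(embedding_profiles,
                                           signature_profiles) {
  ids <- intersect(names(embedding_profiles), names(signature_profiles))
  if (!length(ids)) stop("no shared compound ids between the profile lists")
  rows <- lapply(ids, function(cid) {
    e <- embedding_profiles[[cid]]; s <- signature_profiles[[cid]]
    genes <- intersect(e$gene, s$gene)
    if (length(genes) < 3)
      return(data.frame(compound_id = cid, r = NA_real_,
                        n_genes = length(genes), stringsAsFactors = FALSE))
    r <- stats::cor(e$score[match(genes, e$gene)],
                    s$score[match(genes, s$gene)], method = "pearson")
    data.frame(compound_id = cid, r = r, n_genes = length(genes),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  ok <- per$r[!is.na(per$r)]
  list(per_compound = per,
       summary = list(mean = mean(ok), sd = stats::sd(ok), n = length(ok)))
}

#' Aggregate evaluation report
#'
#' Bundles the per-compound true-pathway p-values and AUROCs with their
#' medians for one evaluation stratum (all / unseen / unseen-hard /
#' anticancer / custom).
#'
#' @param pvalues output of [true_pathway_pvalues()].
#' @param aurocs output of [fdr_threshold_auroc()] (optional).
#' @param stratum label for the compound stratum.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(pvalues, aurocs = NULL, stratum = "all") {
  ev <- pvalues[pvalues$evaluable, , drop = FALSE]
  out <- list(stratum = stratum,
              pvalues = pvalues,
              aurocs = aurocs,
              median_p = stats::median(ev$p_value),
              n_compounds = length(unique(pvalues$compound_id)),
              n_not_evaluable = sum(!pvalues$evaluable),
              median_auroc = if (!is.null(aurocs) && nrow(aurocs))
                stats::median(aurocs$auroc) else NA_real_)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report [", x$stratum, "]: ", x$n_compounds, " compounds\n",
      sep = "")
  cat(sprintf("  median true-pathway p-value: %.4g  (%d not evaluable)\n",
              x$median_p, x$n_not_evaluable))
  if (!is.na(x$median_auroc))
    cat(sprintf("  median AUROC: %.3f over %d compounds\n",
                x$median_auroc, nrow(x$aurocs)))
  invisible(x)
}
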