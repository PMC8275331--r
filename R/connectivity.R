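#' Per-gene connectivity between a query and a genetic-perturbation bank
#'
#' The connectivity score of compound `c` with gene `g` is the maximum
#' cosine similarity between the compound's (embedding or raw-signature)
#' vector and any of the gene's genetic-perturbation vectors:
#' `S[c, g] = max_i sim(z_c, z_g_i)`, where `i` runs over all replicate GP
#' signatures targeting `g` -- knock-down, knock-out and over-expression
#' columns pooled before the max.
#'
#' @param query numeric vector: the compound's embedding (embedding mode) or
#'   raw signature (raw mode).
#' @param gp_vectors numeric matrix of the gene's GP vectors, one per row.
#' @return `gene_connectivity`: the maximum cosine similarity (a scalar in
#'   `[-1, 1]`).
#' @rdname connectivity
#' @export
gene_connectivity <- function(query, gp_vectors) {
  if (!is.matrix(gp_vectors)) gp_vectors <- matrix(gp_vectors, nrow = 1)
  if (nrow(gp_vectors) == 0)
    stop("no genetic-perturbation vectors for this gene")
  max(cosine_matrix(matrix(query, nrow = 1), gp_vectors))
}

#' @param bank an [embedding_bank] restricted to `gp_signature` entries (for
#'   `connectivity_profile`).
#' @param compound_id label recorded on the profile.
#' @return `connectivity_profile`: an object of class
#'   `connectivity_profile` -- a data.frame with columns `gene`, `score`,
#'   `best_sample` (the first sample attaining the max), sorted by gene id,
#'   with attributes `compound_id` and `mode`.
#' @rdname connectivity
#' @export
connectivity_profile <- function(query, bank, compound_id = "query") {
  stopifnot(inherits(bank, "embedding_bank"))
  if (!all(bank$meta$provenance == "gp_signature"))
    stop("bank must contain gp_signature entries only")
  if (nrow(bank$vectors) == 0) stop("empty embedding bank")
  .profile_from_vectors(query, bank$vectors, bank$meta$target_gene,
                        compound_id, mode = "embedding")
}

#' Raw-signature connectivity (TS-connectivity baseline)
#'
#' Identical max-over-replicates algorithm, but cosine similarities are
#' taken in raw signature space (e.g. 978-d landmark profiles) between the
#' compound's actual signature and the GP signature columns.
#'
#' @param compound_signature numeric vector in signature space.
#' @param gp a [signature_matrix] of genetic-perturbation columns.
#' @rdname connectivity
#' @export
raw_signature_connectivity <- function(compound_signature, gp,
                                       compound_id = "query") {
  stopifnot(inherits(gp, "signature_matrix"))
  cm <- gp$column_meta
  if (any(cm$pert_type == "compound"))
    stop("'gp' contains compound columns; pass genetic perturbations only")
  .profile_from_vectors(compound_signature, t(gp$values), cm$target_gene,
                        compound_id, mode = "raw_signature")
}

# shared core of both modes: max cosine per target gene over replicate rows
.profile_from_vectors <- function(query, vectors, target_gene, compound_id,
                                  mode) {
  if (length(query) != ncol(vectors))
    stop("query has length ", length(query), " but GP vectors have ",
         ncol(vectors))
  sims <- drop(cosine_matrix(matrix(query, nrow = 1), vectors))
  genes <- sort(unique(target_gene))
  idx <- split(seq_along(sims), target_gene)
  score <- vapply(genes, function(g) max(sims[idx[[g]]]), numeric(1))
  best <- vapply(genes, function(g) {
    i <- idx[[g]][which.max(sims[idx[[g]]])]
    rownames(vectors)[i]
  }, "")
  structure(data.frame(gene = genes, score = unname(score),
                       best_sample = unname(best), stringsAsFactors = FALSE,
                       row.names = NULL),
            compound_id = compound_id, mode = mode,
            class = c("connectivity_profile", "data.frame"))
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("connectivity_profile for '", attr(x, "compound_id"), "' (",
      attr(x, "mode"), " mode): ", nrow(x), " genes, score range [",
      sprintf("%.3f", min(x$score)), ", ", sprintf("%.3f", max(x$score)),
      "]\n", sep = "")
  invisible(x)
}

#' Connectivity profiles for many query vectors
#'
#' @param queries numeric matrix, one query per row (rownames = compound
#'   ids).
#' @param bank an [embedding_bank] of `gp_signature` entries.
#' @return Named list of [connectivity_profile] objects.
#' @export
connectivity_profiles <- function(queries, bank) {
  stopifnot(is.matrix(queries), !is.null(rownames(queries)))
  out <- lapply(rownames(queries), function(id)
    connectivity_profile(queries[id, ], bank, compound_id = id))
  names(out) <- rownames(queries)
  out
}

#' Write connectivity profiles to long-format TSV
#'
#' Columns: `compound_id`, `gene`, `score`, `best_sample`.
#'
#' @param profiles a list of [connectivity_profile] objects.
#' @param path output path.
#' @export
write_connectivity_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, function(p)
    data.frame(compound_id = attr(p, "compound_id"), gene = p$gene,
               score = sprintf(.num_fmt, p$score),
               best_sample = p$best_sample, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
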