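#' Embedding bank
#'
#' An `embedding_bank` stores id -> embedding vectors together with their
#' provenance: `structure` (compound structure embedding),
#' `compound_signature`, or `gp_signature` (genetic-perturbation signature
#' embedding, which additionally carries `target_gene` and `pert_type`).
#'
#' @param vectors numeric matrix, one embedding per row, rownames = entry
#'   ids.
#' @param provenance one of `"structure"`, `"compound_signature"`,
#'   `"gp_signature"`, recycled or per-entry.
#' @param target_gene,pert_type per-entry metadata, required when provenance
#'   is `gp_signature`.
#' @return An object of class `embedding_bank`.
#' @export
embedding_bank <- function(vectors, provenance,
                           target_gene = NA_character_,
                           pert_type = NA_character_) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  n <- nrow(vectors)
  meta <- data.frame(entry_id = rownames(vectors),
                     provenance = rep_len(provenance, n),
                     target_gene = rep_len(target_gene, n),
                     pert_type = rep_len(pert_type, n),
                     stringsAsFactors = FALSE)
  ok <- c("structure", "compound_signature", "gp_signature")
  if (!all(meta$provenance %in% ok))
    stop("provenance must be one of: ", paste(ok, collapse = ", "))
  gp <- meta$provenance == "gp_signature"
  if (any(gp & (is.na(meta$target_gene) | meta$target_gene == "")))
    stop("gp_signature entries require a target_gene")
  structure(list(vectors = vectors, meta = meta), class = "embedding_bank")
}

#' @export
print.embedding_bank <- function(x, ...) {
  cat("embedding_bank: ", nrow(x$vectors), " entries x ", ncol(x$vectors),
      " dims (", paste(names(table(x$meta$provenance)),
                       table(x$meta$provenance), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.embedding_bank <- function(x) dim(x$vectors)

#' Embed genetic-perturbation signatures into the coembedding space
#'
#' Applies the fitted signature encoder to every genetic-perturbation column
#' of `gp` and returns an [embedding_bank] with provenance `gp_signature`,
#' carrying each column's target gene and perturbation type.
#'
#' @param model a fitted [moable] model.
#' @param gp a [signature_matrix] of knock-down / knock-out /
#'   over-expression columns (compound columns are rejected).
#' @return An `embedding_bank` with one entry per GP sample column.
#' @export
embed_gp_signatures <- function(model, gp) {
  stopifnot(inherits(model, "moable"), inherits(gp, "signature_matrix"))
  cm <- gp$column_meta
  if (any(cm$pert_type == "compound"))
    stop("'gp' contains compound columns; pass genetic perturbations only ",
         "(see gp_columns())")
  Z <- predict(model, gp, type = "signature")
  embedding_bank(Z, provenance = "gp_signature",
                 target_gene = cm$target_gene, pert_type = cm$pert_type)
}

#' Read / write an embedding bank as TSV
#'
#' Long header `entry_id, provenance, target_gene, pert_type, e1..eD`;
#' values written with 10 significant digits, so write -> read -> write is
#' byte-stable.
#'
#' @param bank an [embedding_bank].
#' @param path file path.
#' @rdname embedding_bank_io
#' @export
write_embedding_bank <- function(bank, path) {
  stopifnot(inherits(bank, "embedding_bank"))
  d <- ncol(bank$vectors)
  header <- paste(c("entry_id", "provenance", "target_gene", "pert_type",
                    paste0("e", seq_len(d))), collapse = "\t")
  rows <- paste(bank$meta$entry_id, bank$meta$provenance,
                ifelse(is.na(bank$meta$target_gene), "", bank$meta$target_gene),
                ifelse(is.na(bank$meta$pert_type), "", bank$meta$pert_type),
                apply(bank$vectors, 1, function(r)
                  paste(sprintf(.num_fmt, r), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname embedding_bank_io
#' @export
read_embedding_bank <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ecols <- grep("^e[0-9]+$", names(tab))
  v <- as.matrix(tab[, ecols, drop = FALSE])
  rownames(v) <- tab$entry_id
  colnames(v) <- NULL
  embedding_bank(v, provenance = tab$provenance,
                 target_gene = ifelse(tab$target_gene == "" |
                                        is.na(tab$target_gene),
                                      NA_character_, tab$target_gene),
                 pert_type = ifelse(tab$pert_type == "" |
                                      is.na(tab$pert_type),
                                    NA_character_, tab$pert_type))
}

#' Save / load a fitted model archive
#'
#' The archive is a directory holding a parameter blob (`params.rds`) and a
#' human-readable `meta.json` with the dimensions, margin, seed and full
#' training configuration, plus the training log as TSV.
#'
#' @param model a fitted [moable] model.
#' @param dir archive directory (created if missing).
#' @rdname moable_archive
#' @export
write_moable <- function(model, dir) {
  stopifnot(inherits(model, "moable"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(str_net = model$str_net, sig_net = model$sig_net),
          file.path(dir, "params.rds"))
  meta <- c(model$config[setdiff(names(model$config), "validation")],
            list(n_bits = model$n_bits, sig_dim = model$sig_dim,
                 epochs_run = nrow(model$log)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(dir, "meta.json"))
  utils::write.table(model$log, file.path(dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname moable_archive
#' @export
read_moable <- function(dir) {
  params <- readRDS(file.path(dir, "params.rds"))
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  log <- utils::read.delim(file.path(dir, "training_log.tsv"))
  structure(list(str_net = params$str_net, sig_net = params$sig_net,
                 log = log, n_bits = meta$n_bits, sig_dim = meta$sig_dim,
                 output_dim = meta$output_dim,
                 config = meta[setdiff(names(meta),
                                       c("n_bits", "sig_dim", "epochs_run"))]),
            class = "moable")
}
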