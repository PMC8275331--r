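#' Signature matrix container
#'
#' A `signature_matrix` holds a genes x samples real matrix of transcriptomic
#' signatures (differential expression profiles, by default over the 978
#' L1000 landmark genes) together with per-sample metadata: the perturbagen
#' identifier, the perturbation type, and -- for genetic perturbations -- the
#' target gene.
#'
#' @param values numeric matrix, genes in rows, samples in columns.  Row and
#'   column names are used as gene and sample identifiers (both required).
#' @param column_meta data.frame with one row per sample.  Recognised columns:
#'   `sample_id` (must match `colnames(values)`), `perturbagen_id`,
#'   `pert_type` (one of `"compound"`, `"knock-down"`, `"knock-out"`,
#'   `"over-expression"`), `target_gene` (required, non-empty, for every
#'   genetic-perturbation column), `cell_line` (optional).  If `NULL`, all
#'   samples are taken to be compound signatures.
#'
#' @return An object of class `signature_matrix`: a list with elements
#'   `values` and `column_meta`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' sm <- signature_matrix(m)
#' dim(sm)
#' @export
signature_matrix <- function(values, column_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row names (gene ids) and column names (sample ids)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("signature values must all be finite")
  if (is.null(column_meta)) {
    column_meta <- data.frame(sample_id = colnames(values),
                              perturbagen_id = colnames(values),
                              pert_type = "compound",
                              target_gene = "",
                              cell_line = "",
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(column_meta) || is.null(column_meta$sample_id))
    stop("'column_meta' must be a data.frame with a 'sample_id' column")
  for (col in c("perturbagen_id", "pert_type", "target_gene", "cell_line")) {
    if (is.null(column_meta[[col]]))
      column_meta[[col]] <- if (col == "pert_type") "compound" else ""
  }
  column_meta <- column_meta[match(colnames(values), column_meta$sample_id),
                             c("sample_id", "perturbagen_id", "pert_type",
                               "target_gene", "cell_line"),
                             drop = FALSE]
  if (anyNA(column_meta$sample_id))
    stop("column_meta is missing entries for samples: ",
         paste(setdiff(colnames(values), column_meta$sample_id), collapse = ", "))
  rownames(column_meta) <- NULL
  ok_types <- c("compound", "knock-down", "knock-out", "over-expression")
  bad <- setdiff(unique(column_meta$pert_type), ok_types)
  if (length(bad))
    stop("unknown pert_type value(s): ", paste(bad, collapse = ", "))
  gp <- column_meta$pert_type != "compound"
  missing_target <- gp & (is.na(column_meta$target_gene) | column_meta$target_gene == "")
  if (any(missing_target))
    stop("genetic-perturbation column(s) lacking target_gene: ",
         paste(column_meta$sample_id[missing_target], collapse = ", "))
  structure(list(values = values, column_meta = column_meta),
            class = "signature_matrix")
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

#' @export
print.signature_matrix <- function(x, ...) {
  gp <- sum(x$column_meta$pert_type != "compound")
  cat("signature_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", gp, " genetic-perturbation, ",
      ncol(x$values) - gp, " compound)\n", sep = "")
  invisible(x)
}

#' Gene and sample identifiers of a signature matrix
#' @param x a `signature_matrix`.
#' @return Character vector of identifiers.
#' @rdname signature_ids
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname signature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a signature matrix by sample
#' @param x a `signature_matrix`.
#' @param samples character vector of sample ids (or logical/integer index).
#' @return A `signature_matrix` restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "signature_matrix"))
  if (is.character(samples)) {
    miss <- setdiff(samples, colnames(x$values))
    if (length(miss))
      stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  }
  v <- x$values[, samples, drop = FALSE]
  signature_matrix(v, x$column_meta[match(colnames(v), x$column_meta$sample_id), ,
                                    drop = FALSE])
}

#' Extract genetic-perturbation columns
#'
#' @param x a `signature_matrix`.
#' @return A `signature_matrix` containing only knock-down, knock-out and
#'   over-expression columns.
#' @export
gp_columns <- function(x) {
  stopifnot(inherits(x, "signature_matrix"))
  keep <- x$column_meta$pert_type != "compound"
  if (!any(keep)) stop("no genetic-perturbation columns present")
  subset_samples(x, x$column_meta$sample_id[keep])
}
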