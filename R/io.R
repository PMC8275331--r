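# Readers/writers for the text formats the pipeline touches: GCT 1.2 for
# signature matrices (with a TSV sidecar for per-sample metadata), GMT for
# pathway gene sets, and simple TSV dialects for fingerprints, SMILES and
# MoA truth labels.  Numeric values are written with %.10g, so write->read
# round-trips are exact to 10 significant digits.

.num_fmt <- "%.10g"

default_meta_path <- function(path) paste0(path, ".meta.tsv")

#' Read a signature matrix from a GCT 1.2 text file
#'
#' Parses the standard GCT 1.2 layout: a `#1.2` version line, a
#' `<n_genes>\t<n_samples>` dimension line, a header line
#' (`NAME`, `Description`, sample ids), and one row per gene.  Per-sample
#' metadata (perturbagen id, perturbation type, target gene, cell line) is
#' read from a sidecar TSV (columns `sample_id`, `perturbagen_id`,
#' `pert_type`, `target_gene`, `cell_line`); without a sidecar all columns
#' are treated as compound signatures.
#'
#' @param path path to the GCT file.
#' @param meta_path path to the metadata sidecar TSV; defaults to
#'   `<path>.meta.tsv` and is optional.
#' @return A [signature_matrix].
#' @seealso [write_signature_gct()]
#' @export
read_signature_gct <- function(path, meta_path = default_meta_path(path)) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed GCT file '", path, "': fewer than 3 lines")
  if (!grepl("^#1\\.[23]$", lines[1]))
    stop("malformed GCT version line: '", lines[1], "'")
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  ndim <- suppressWarnings(as.integer(dims))
  if (length(ndim) < 2 || anyNA(ndim[1:2]))
    stop("malformed GCT dimension line: '", lines[2], "'")
  ng <- ndim[1]; ns <- ndim[2]
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != ns + 2)
    stop("GCT header has ", length(header) - 2, " sample columns, expected ", ns)
  samples <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng)
    stop("GCT declares ", ng, " data rows but file contains ", length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ns + 2))
    stop("GCT data row ", which(nf != ns + 2)[1], " has ",
         nf[which(nf != ns + 2)[1]] - 2, " values, expected ", ns)
  genes <- vapply(fields, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-(1:2)]), numeric(ns)))
  vals <- if (ns == 1) matrix(vals, nrow = 1) else t(vals)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value in GCT at gene '", genes[idx[1]],
         "', sample '", samples[idx[2]], "'")
  }
  dimnames(vals) <- list(genes, samples)
  meta <- NULL
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  signature_matrix(vals, meta)
}

#' Write a signature matrix as GCT 1.2 plus a metadata sidecar
#'
#' @param x a [signature_matrix].
#' @param path output GCT path.
#' @param meta_path output sidecar TSV path (default `<path>.meta.tsv`).
#' @return `path`, invisibly.
#' @export
write_signature_gct <- function(x, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(x, "signature_matrix"))
  v <- x$values
  rows <- paste(rownames(v), "na",
                apply(v, 1, function(r) paste(sprintf(.num_fmt, r), collapse = "\t")),
                sep = "\t")
  writeLines(c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("NAME", "Description", colnames(v)), collapse = "\t"),
               rows),
             path)
  utils::write.table(x$column_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' Each line is `pathway_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within one line are deduplicated; lines with fewer than
#' three fields (no genes) are an error.
#'
#' @param path path to the GMT file.
#' @param source_name label recorded on the collection (defaults to the file
#'   name).
#' @return A `pathway_collection`: a named list of character vectors of gene
#'   symbols, with attribute `source_name`.
#' @export
read_gmt <- function(path, source_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields (no genes): '",
         lines[short[1]], "'")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_collection(sets, source_name)
}

#' Construct a pathway collection
#'
#' @param sets named list of character vectors (gene symbols per pathway).
#' @param source_name provenance label.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(sets, source_name = "unnamed") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every pathway needs a non-empty id")
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (any(vapply(sets, function(s) any(!nzchar(s)), TRUE)))
    stop("gene symbols must be non-empty strings")
  structure(lapply(sets, as.character),
            source_name = source_name, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection '", attr(x, "source_name"), "': ", length(x),
      " sets, sizes ", min(lengths(x)), "-", max(lengths(x)), "\n", sep = "")
  invisible(x)
}

#' Write a pathway collection to GMT
#' @param x a `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  writeLines(vapply(names(x), function(id)
    paste(c(id, "na", x[[id]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read / write fingerprint TSV
#'
#' Two tab-separated columns: compound id and the fingerprint as a string of
#' `0`/`1` characters (no separators), one compound per line, with a header.
#'
#' @param path file path.
#' @return `read_fingerprints`: a 0/1 integer matrix, compounds in rows
#'   (rownames = compound ids).
#' @rdname fingerprint_io
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop("fingerprint TSV needs columns: compound_id, bits")
  bits <- strsplit(tab[[2]], "", fixed = TRUE)
  n <- lengths(bits)
  if (length(unique(n)) != 1)
    stop("fingerprints of unequal length in '", path, "'")
  m <- do.call(rbind, lapply(bits, function(b) as.integer(b)))
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("fingerprint strings must contain only 0/1 characters")
  rownames(m) <- tab[[1]]
  if (anyDuplicated(rownames(m)))
    stop("duplicate compound id(s) in fingerprint TSV")
  m
}

#' @param fps 0/1 matrix, compounds in rows, rownames = compound ids.
#' @rdname fingerprint_io
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(is.matrix(fps), !is.null(rownames(fps)))
  writeLines(c("compound_id\tbits",
               paste(rownames(fps),
                     apply(fps, 1, paste, collapse = ""), sep = "\t")),
             path)
  invisible(path)
}

#' Read a SMILES table (`compound_id<TAB>smiles`, with header)
#' @param path file path.
#' @return data.frame with columns `compound_id`, `smiles`.
#' @export
read_smiles_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("SMILES TSV needs columns: compound_id, smiles")
  names(tab)[1:2] <- c("compound_id", "smiles")
  tab[1:2]
}

#' Read / write MoA truth labels
#'
#' Truth labels are a two-column TSV `compound_id<TAB>pathway_id` (header
#' included); a compound may appear on several lines.
#'
#' @param path file path.
#' @return `read_moa_truth`: a named list mapping compound id to a character
#'   vector of true pathway ids.
#' @rdname moa_truth_io
#' @export
read_moa_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop("truth TSV needs columns: compound_id, pathway_id")
  split(tab[[2]], factor(tab[[1]], levels = unique(tab[[1]])))
}

#' @param truth named list compound id -> character vector of pathway ids.
#' @rdname moa_truth_io
#' @export
write_moa_truth <- function(truth, path) {
  cid <- rep(names(truth), lengths(truth))
  writeLines(c("compound_id\tpathway_id",
               paste(cid, unlist(truth, use.names = FALSE), sep = "\t")),
             path)
  invisible(path)
}
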