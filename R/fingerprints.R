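#' Convert SMILES to an extended-connectivity fingerprint
#'
#' Computes a circular-substructure (ECFP) presence fingerprint through the
#' OpenBabel backend (package \pkg{ChemmineOB}).  The backend emits a
#' 4096-bit ECFP; when `n_bits` is smaller the vector is folded by bitwise
#' OR of congruent positions, the usual fixed-length hashing convention.
#' The rest of the pipeline only consumes 0/1 vectors, so precomputed
#' fingerprints (see [read_fingerprints()]) work when no cheminformatics
#' backend is installed.
#'
#' @param smiles character vector of SMILES strings.
#' @param n_bits fingerprint length (default 2048).
#' @param radius circular neighbourhood radius; 2 is the ECFP4 convention
#'   (diameter 4).  Supported: 1, 2, 3.
#' @return A 0/1 integer matrix with one row per input SMILES (rownames =
#'   `names(smiles)` if set, else the SMILES themselves).
#' @export
smiles_to_fingerprint <- function(smiles, n_bits = 2048L, radius = 2L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("no cheminformatics backend available (package 'ChemmineOB' not ",
         "installed); supply precomputed fingerprints via read_fingerprints()",
         call. = FALSE)
  if (!radius %in% 1:3)
    stop("'radius' must be 1, 2 or 3 (ECFP2/ECFP4/ECFP6)")
  fp_name <- paste0("ECFP", 2L * radius)
  rows <- lapply(seq_along(smiles), function(i) {
    s <- smiles[[i]]
    full <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", s, function(m) ChemmineOB::fingerprint_OB(list(m), fp_name)))[[1]],
      error = function(e)
        stop("could not parse SMILES '", s, "': ", conditionMessage(e),
             call. = FALSE))
    fold_bits(as.integer(full != 0), n_bits)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (!is.null(names(smiles))) names(smiles) else unlist(smiles)
  m
}

# fold a 0/1 vector to length n_bits by OR of congruent positions
fold_bits <- function(bits, n_bits) {
  if (length(bits) <= n_bits)
    return(c(bits, integer(n_bits - length(bits))))
  idx <- (seq_along(bits) - 1L) %% n_bits
  as.integer(tapply(bits, idx, max))
}

#' Tanimoto similarity between binary fingerprints
#'
#' `tanimoto_similarity` computes |a AND b| / |a OR b| for two 0/1 vectors;
#' `tanimoto_matrix` computes it for all pairs of rows of two matrices.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return A similarity in `[0, 1]`; two all-zero fingerprints have
#'   similarity 0 by convention.
#' @rdname tanimoto
#' @export
tanimoto_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' @param x,y 0/1 matrices, fingerprints in rows.
#' @return `tanimoto_matrix`: an `nrow(x)` x `nrow(y)` similarity matrix.
#' @rdname tanimoto
#' @export
tanimoto_matrix <- function(x, y) {
  stopifnot(ncol(x) == ncol(y))
  inter <- tcrossprod(x, y)
  uni <- outer(rowSums(x), rowSums(y), `+`) - inter
  s <- inter / uni
  s[uni == 0] <- 0
  s
}

#' Stratify evaluation compounds by structural similarity to training set
#'
#' For each evaluation compound, computes the maximum Tanimoto similarity to
#' any training compound and labels it `unseen_hard` when that maximum falls
#' below `threshold`.
#'
#' @param train_fps training fingerprints (0/1 matrix, rownames = ids).
#' @param eval_fps evaluation fingerprints (0/1 matrix, rownames = ids).
#' @param threshold similarity cutoff (default 0.3).
#' @return data.frame with columns `compound_id`, `max_tanimoto`,
#'   `unseen_hard`.
#' @export
tanimoto_stratify <- function(train_fps, eval_fps, threshold = 0.3) {
  if (!is.matrix(train_fps) || nrow(train_fps) == 0)
    stop("empty training fingerprint set")
  sims <- tanimoto_matrix(eval_fps, train_fps)
  mx <- apply(sims, 1, max)
  data.frame(compound_id = rownames(eval_fps),
             max_tanimoto = unname(mx),
             unseen_hard = unname(mx < threshold),
             stringsAsFactors = FALSE)
}
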