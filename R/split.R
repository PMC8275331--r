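#' Compound-disjoint train/validation/test split
#'
#' Partitions compounds (not individual signatures) into train, validation
#' and test sets, so that all replicate signatures of one compound fall into
#' the same split and no compound is shared between splits.  Split sizes
#' follow the requested fractions by the largest-remainder rule, ties broken
#' toward the earlier-listed split; every split is guaranteed at least one
#' compound when fractions are positive.
#'
#' @param compound_ids character vector of unique compound identifiers.
#' @param fractions numeric triple (train, validation, test); must be
#'   positive and sum to 1 (tolerance 1e-9).
#' @param seed integer seed; the assignment is a seeded permutation, so the
#'   same call always yields the same partition.
#' @return A list with character-vector elements `train`, `validation`,
#'   `test` forming a partition of `compound_ids`.
#' @examples
#' split_compounds(paste0("c", 1:10), c(0.7, 0.15, 0.15), seed = 1)
#' @export
split_compounds <- function(compound_ids, fractions = c(0.7, 0.15, 0.15),
                            seed = 1L) {
  if (anyDuplicated(compound_ids))
    stop("compound ids must be unique")
  n <- length(compound_ids)
  if (n < 3)
    stop("need at least 3 compounds to form 3 splits, got ", n)
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("'fractions' must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must sum to 1")
  sizes <- largest_remainder(n, fractions)
  # every split non-empty: move from the largest split if needed
  while (any(sizes == 0)) {
    sizes[which.max(sizes)] <- max(sizes) - 1L
    sizes[which(sizes == 0)[1]] <- 1L
  }
  perm <- with_seed(seed, sample.int(n))
  shuffled <- compound_ids[perm]
  ends <- cumsum(sizes)
  list(train      = sort(shuffled[seq_len(sizes[1])]),
       validation = sort(shuffled[seq.int(ends[1] + 1L, ends[2])]),
       test       = sort(shuffled[seq.int(ends[2] + 1L, ends[3])]))
}

# largest-remainder apportionment of n into round(n*f) seats;
# ties in the remainders go to the earlier-listed fraction
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Evaluate 'expr' under a temporary, seeded RNG state; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
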