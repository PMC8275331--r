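#' Cosine similarity
#'
#' `cosine_similarity(u, v)` computes `u . v / (||u|| ||v||)` for two equal
#' length vectors; `cosine_matrix(x, y)` computes all pairwise similarities
#' between the rows of two matrices.  Similarity of a zero vector is
#' undefined and raises an error (it is never silently reported as 0).
#'
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return A similarity in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2), c(2, 4))  # 1: scale invariant
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors differ in length: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero vector")
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

#' @param x,y numeric matrices with the same number of columns.
#' @return `cosine_matrix`: an `nrow(x)` x `nrow(y)` matrix of similarities.
#' @rdname cosine_similarity
#' @export
cosine_matrix <- function(x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (ncol(x) != ncol(y))
    stop("matrices differ in column count: ", ncol(x), " vs ", ncol(y))
  nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
  if (any(nx == 0) || any(ny == 0))
    stop("cosine similarity undefined for a zero vector")
  s <- tcrossprod(x, y) / outer(nx, ny)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Triplet hinge loss
#'
#' The per-triplet loss `max(sim_neg - sim_pos + margin, 0)`: zero exactly
#' when the anchor is closer (by cosine similarity) to its positive than to
#' the negative by at least the margin.  Minimizing the summed hinge is
#' equivalent, up to sign and an additive constant, to maximizing the
#' saturating objective `sum min(sim_pos - sim_neg - margin, 0)`; the hinge
#' form is the one optimized during training.
#'
#' @param sim_pos,sim_neg cosine similarities in `[-1, 1]` (vectorized).
#' @param margin non-negative margin (alpha), default 0.2.
#' @return Non-negative loss value(s).
#' @examples
#' triplet_loss(0.9, 0.1, 0.2)   # 0: margin satisfied
#' triplet_loss(-0.2, 0.4, 0.1)  # 0.7
#' @export
triplet_loss <- function(sim_pos, sim_neg, margin = 0.2) {
  stopifnot(is.finite(margin), margin >= 0)
  if (any(sim_pos < -1 - 1e-12 | sim_pos > 1 + 1e-12) ||
      any(sim_neg < -1 - 1e-12 | sim_neg > 1 + 1e-12))
    stop("similarities must lie in [-1, 1]")
  pmax(sim_neg - sim_pos + margin, 0)
}
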