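# Minimal multilayer-perceptron machinery for the two encoders: seeded
# fan-in-uniform initialization, ReLU forward pass with caches, exact
# backpropagation, and Adam.  Written in base R matrix algebra; all heavy
# lifting is BLAS matrix products.  Consumes the caller's RNG stream only in
# mlp_init (the fit function runs everything under one seeded stream).

mlp_init <- function(input_dim, layer_dims) {
  dims <- c(input_dim, layer_dims)
  layers <- vector("list", length(layer_dims))
  for (l in seq_along(layer_dims)) {
    fan_in <- dims[l]
    bound <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * dims[l + 1], -bound, bound),
                 fan_in, dims[l + 1]),
      b = stats::runif(dims[l + 1], -bound, bound))
  }
  structure(list(layers = layers, input_dim = input_dim,
                 layer_dims = layer_dims),
            class = "moable_mlp")
}

# forward pass; ReLU between layers, linear final layer (embeddings must be
# able to take negative values so cosine similarity spans [-1, 1]).
mlp_forward <- function(net, X, keep_cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$input_dim)
    stop("input has ", ncol(X), " features but the encoder expects ",
         net$input_dim)
  L <- length(net$layers)
  acts <- if (keep_cache) vector("list", L + 1) else NULL
  h <- X
  if (keep_cache) acts[[1]] <- h
  for (l in seq_len(L)) {
    z <- h %*% net$layers[[l]]$W
    z <- sweep(z, 2, net$layers[[l]]$b, `+`)
    h <- if (l < L) pmax(z, 0) else z
    if (keep_cache) acts[[l + 1]] <- h
  }
  if (keep_cache) list(out = h, acts = acts) else h
}

# backprop of dLoss/dOutput through the cached forward pass;
# returns per-layer gradients in the same shapes as the parameters.
mlp_backward <- function(net, cache, g_out) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- g_out
  for (l in rev(seq_len(L))) {
    h_in <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(h_in, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(net$layers[[l]]$W)
      delta <- delta * (cache$acts[[l]] > 0)   # ReLU mask of layer l-1 output
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(net, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

# Mean triplet hinge loss over a batch, plus its gradient with respect to
# the anchor (signature) and structure embeddings.
# Zs: anchors (B x d), Zc: structure embeddings, row i the positive of
# anchor i; neg_idx[i] indexes the negative row of Zc.
# loss = mean_i max(sim(Zs_i, Zc_neg(i)) - sim(Zs_i, Zc_i) + margin, 0)
# (the saturating maximization of sum_i min(sim_pos - sim_neg - margin, 0)
#  is this hinge minimization up to sign and the additive constant).
batch_triplet_loss <- function(Zs, Zc, neg_idx, margin, grad = TRUE) {
  B <- nrow(Zs)
  ns <- sqrt(rowSums(Zs^2))
  nc <- sqrt(rowSums(Zc^2))
  if (any(ns == 0) || any(nc == 0))
    stop("cosine similarity undefined: zero embedding vector in batch")
  dot_pos <- rowSums(Zs * Zc)
  sim_pos <- dot_pos / (ns * nc)
  Zn <- Zc[neg_idx, , drop = FALSE]
  nn <- nc[neg_idx]
  dot_neg <- rowSums(Zs * Zn)
  sim_neg <- dot_neg / (ns * nn)
  hinge <- pmax(sim_neg - sim_pos + margin, 0)
  loss <- mean(hinge)
  if (!grad)
    return(list(loss = loss, hinge = hinge,
                sim_pos = sim_pos, sim_neg = sim_neg))
  act <- as.numeric(hinge > 0) / B            # d loss / d hinge_i
  # d sim(u,v)/du = v/(|u||v|) - sim * u/|u|^2
  d_pos_dZs <- Zc / (ns * nc) - (sim_pos / ns^2) * Zs
  d_pos_dZc <- Zs / (ns * nc) - (sim_pos / nc^2) * Zc
  d_neg_dZs <- Zn / (ns * nn) - (sim_neg / ns^2) * Zs
  d_neg_dZn <- Zs / (ns * nn) - (sim_neg / nn^2) * Zn
  gZs <- act * (d_neg_dZs - d_pos_dZs)
  gZc <- -act * d_pos_dZc
  gZc_neg <- rowsum(act * d_neg_dZn, neg_idx)
  rows <- as.integer(rownames(gZc_neg))
  gZc[rows, ] <- gZc[rows, , drop = FALSE] + gZc_neg
  list(loss = loss, hinge = hinge, gZs = gZs, gZc = gZc,
       sim_pos = sim_pos, sim_neg = sim_neg)
}
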