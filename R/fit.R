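#' Fit the compound-structure / signature coembedding model
#'
#' Trains two multilayer-perceptron encoders -- `f_str` mapping ECFP
#' fingerprint vectors and `f_sig` mapping transcriptomic signature vectors
#' into one shared embedding space (default 256-d) -- with a
#' cosine-similarity triplet loss.  For each training instance the
#' signature embedding is the anchor, the structure embedding of the same
#' compound the positive, and the structure embedding of another compound in
#' the minibatch the negative; the minibatch loss is the mean of the
#' per-triplet hinges `max(sim_neg - sim_pos + margin, 0)`.  Optimization
#' uses Adam.  Every signature replicate is its own anchor, so compounds
#' with many replicates are seen proportionally often.
#'
#' Both encoders are four weight layers with rectified-linear activations
#' between layers and a linear final layer (defaults
#' 2048-2048-512-256-256 for structures and 978-512-512-256-256 for
#' signatures); embeddings are not length-normalized -- cosine similarity
#' handles scale.
#'
#' @param fingerprints 0/1 matrix, one row per compound, rownames = compound
#'   ids.
#' @param signatures a [signature_matrix] of compound signatures; each
#'   column's `perturbagen_id` must be a rowname of `fingerprints`.  Columns
#'   of compounds absent from `fingerprints` are an error.
#' @param validation compound ids held out for validation-loss early
#'   stopping, or `NULL` to train for `max_epochs` without early stopping.
#' @param hidden_str,hidden_sig hidden layer widths of the two encoders.
#' @param output_dim shared embedding dimension (default 256).
#' @param margin triplet margin alpha (default 0.2).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 512; must be >= 2 so a negative
#'   exists).
#' @param max_epochs,patience epoch cap and early-stopping patience on the
#'   validation triplet loss.
#' @param negative negative-sampling strategy: `"random_in_batch"` (one
#'   uniformly drawn other-compound structure per anchor) or
#'   `"hardest_in_batch"` (the most similar other-compound structure).
#' @param seed integer seed controlling initialization, data order and
#'   negative draws; fits are fully reproducible.
#' @param verbose print per-epoch losses.
#'
#' @return An object of class `moable`: list with elements `str_net`,
#'   `sig_net` (encoder parameters), `config`, `log` (data.frame epoch /
#'   train_loss / val_loss), `n_bits`, `sig_dim`, `output_dim`.
#' @seealso [predict.moable()], [embed_gp_signatures()], [write_moable()]
#' @export
moable <- function(fingerprints, signatures, validation = NULL,
                   hidden_str = c(2048, 512, 256),
                   hidden_sig = c(512, 512, 256),
                   output_dim = 256,
                   margin = 0.2, learning_rate = 1e-4, batch_size = 512,
                   max_epochs = 100, patience = 10,
                   negative = c("random_in_batch", "hardest_in_batch"),
                   seed = 1L, verbose = FALSE) {
  negative <- match.arg(negative)
  stopifnot(is.matrix(fingerprints), !is.null(rownames(fingerprints)),
            inherits(signatures, "signature_matrix"),
            batch_size >= 2, margin >= 0, is.finite(margin),
            learning_rate > 0, max_epochs >= 1, patience >= 1)
  cm <- signatures$column_meta
  if (any(cm$pert_type != "compound"))
    stop("'signatures' must contain compound columns only; use ",
         "embed_gp_signatures() for genetic perturbations")
  comp <- cm$perturbagen_id
  unknown <- setdiff(unique(comp), rownames(fingerprints))
  if (length(unknown))
    stop("signature columns for compounds without fingerprints: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (length(unique(comp)) < 2)
    stop("need at least 2 distinct compounds to form triplets")

  X_sig <- t(signatures$values)                       # anchors x sig_dim
  X_str <- fingerprints[comp, , drop = FALSE]         # anchors x n_bits
  is_val <- comp %in% validation
  if (!is.null(validation) && (!any(is_val) || all(is_val)))
    stop("validation split must hold out some, not all, compounds")
  tr <- which(!is_val); va <- which(is_val)

  fit <- with_seed(seed, {
    str_net <- mlp_init(ncol(X_str), c(hidden_str, output_dim))
    sig_net <- mlp_init(ncol(X_sig), c(hidden_sig, output_dim))
    opt_str <- adam_init(str_net); opt_sig <- adam_init(sig_net)
    step <- 0L
    # fixed negative assignment for the validation loss
    val_neg <- if (length(va)) draw_negatives(comp[va]) else integer(0)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    best <- Inf; best_nets <- NULL; wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr)
      batch_losses <- c()
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        cb <- comp[idx]
        if (length(unique(cb)) < 2) {
          warning("skipping a minibatch with a single distinct compound",
                  call. = FALSE)
          next
        }
        neg <- if (negative == "random_in_batch") draw_negatives(cb) else NULL
        fs <- mlp_forward(sig_net, X_sig[idx, , drop = FALSE], keep_cache = TRUE)
        fc <- mlp_forward(str_net, X_str[idx, , drop = FALSE], keep_cache = TRUE)
        if (is.null(neg)) neg <- hardest_negatives(fs$out, fc$out, cb)
        bt <- batch_triplet_loss(fs$out, fc$out, neg, margin)
        if (!is.finite(bt$loss))
          stop("training aborted: non-finite loss at epoch ", epoch,
               " (learning rate too high or degenerate inputs?)")
        step <- step + 1L
        up <- adam_step(sig_net, mlp_backward(sig_net, fs, bt$gZs),
                        opt_sig, step, learning_rate)
        sig_net <- up$net; opt_sig <- up$state
        up <- adam_step(str_net, mlp_backward(str_net, fc, bt$gZc),
                        opt_str, step, learning_rate)
        str_net <- up$net; opt_str <- up$state
        batch_losses <- c(batch_losses, bt$loss)
      }
      vl <- NA_real_
      if (length(va)) {
        Zs <- mlp_forward(sig_net, X_sig[va, , drop = FALSE])
        Zc <- mlp_forward(str_net, X_str[va, , drop = FALSE])
        vl <- batch_triplet_loss(Zs, Zc, val_neg, margin, grad = FALSE)$loss
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", epoch,
                        mean(batch_losses),
                        if (is.na(vl)) "-" else sprintf("%.5f", vl)))
      if (length(va)) {
        if (vl < best - 1e-12) {
          best <- vl; wait <- 0L
          best_nets <- list(str = str_net, sig = sig_net)
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
    if (!is.null(best_nets)) {
      str_net <- best_nets$str; sig_net <- best_nets$sig
    }
    list(str_net = str_net, sig_net = sig_net, log = log)
  })

  structure(list(
    str_net = fit$str_net, sig_net = fit$sig_net, log = fit$log,
    n_bits = ncol(X_str), sig_dim = ncol(X_sig), output_dim = output_dim,
    config = list(hidden_str = hidden_str, hidden_sig = hidden_sig,
                  output_dim = output_dim, margin = margin,
                  learning_rate = learning_rate, batch_size = batch_size,
                  max_epochs = max_epochs, patience = patience,
                  negative = negative, seed = seed,
                  n_anchors = nrow(X_sig),
                  n_compounds = length(unique(comp)),
                  validation = validation)),
    class = "moable")
}

# one uniformly drawn in-batch negative (different compound) per anchor
draw_negatives <- function(comp_batch) {
  vapply(seq_along(comp_batch), function(i) {
    cand <- which(comp_batch != comp_batch[i])
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1))
}

# most-similar other-compound structure embedding per anchor
hardest_negatives <- function(Zs, Zc, comp_batch) {
  S <- cosine_matrix(Zs, Zc)
  S[outer(comp_batch, comp_batch, `==`)] <- -Inf
  max.col(S, ties.method = "first")
}

#' @export
print.moable <- function(x, ...) {
  cat("moable coembedding model\n")
  cat("  structure encoder: ", paste(c(x$n_bits, x$config$hidden_str,
                                       x$output_dim), collapse = "-"), "\n",
      sep = "")
  cat("  signature encoder: ", paste(c(x$sig_dim, x$config$hidden_sig,
                                       x$output_dim), collapse = "-"), "\n",
      sep = "")
  cat("  trained ", nrow(x$log), " epochs on ", x$config$n_anchors,
      " anchors (", x$config$n_compounds, " compounds), margin ",
      x$config$margin, "\n", sep = "")
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final train loss %.5f", last$train_loss))
    if (!is.na(last$val_loss)) cat(sprintf(", val loss %.5f", last$val_loss))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.moable <- function(object, ...) {
  out <- list(config = object$config, log = object$log,
              n_parameters = sum(vapply(c(object$str_net$layers,
                                          object$sig_net$layers),
                                        function(l) length(l$W) + length(l$b),
                                        numeric(1))))
  class(out) <- "summary.moable"
  out
}

#' @export
print.summary.moable <- function(x, ...) {
  cat("moable model:", x$n_parameters, "parameters\n")
  cat("margin", x$config$margin, "| lr", x$config$learning_rate,
      "| batch", x$config$batch_size, "| negatives:", x$config$negative,
      "| seed", x$config$seed, "\n")
  print(utils::tail(x$log, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.moable <- function(object, ...) {
  list(structure_encoder = object$str_net$layers,
       signature_encoder = object$sig_net$layers)
}

#' Training-curve plot
#' @param x a fitted `moable` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.moable <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "triplet loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Embed compounds or signatures with a fitted model
#'
#' Inference is deterministic: the same model and input always produce
#' identical embeddings.  Batched calls equal row-wise single calls.
#'
#' @param object a fitted `moable` model.
#' @param newdata for `type = "structure"`, a 0/1 fingerprint matrix
#'   (compounds in rows); for `type = "signature"`, a [signature_matrix] or
#'   a numeric matrix with samples in rows.
#' @param type which encoder to apply.
#' @param ... unused.
#' @return Numeric matrix of embeddings, one row per input, `output_dim`
#'   columns; rownames carried over from the input.
#' @export
predict.moable <- function(object, newdata,
                           type = c("structure", "signature"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "signature_matrix")) {
    if (type != "signature")
      stop("a signature_matrix can only be embedded with type = 'signature'")
    newdata <- t(newdata$values)
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (nrow(newdata) == 0)
    return(matrix(numeric(0), 0, object$output_dim))
  net <- if (type == "structure") object$str_net else object$sig_net
  out <- mlp_forward(net, newdata)
  rownames(out) <- rownames(newdata)
  out
}
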