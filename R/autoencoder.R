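#' Mask a random subset of non-zero expression entries
#'
#' Self-supervision for the graph auto-encoder: `floor(fraction * nnz)`
#' non-zero entries are sampled uniformly (seeded) and set to zero; the
#' positions and original values are recorded so the reconstruction loss
#' can be evaluated on exactly those entries and the matrix can be
#' restored.
#'
#' @param x `ExpressionMatrix` (or numeric matrix)
#' @param fraction fraction of non-zero entries to mask, in `[0, 1)`
#' @param seed RNG seed for the mask draw
#' @return list with `masked` (matrix with masked entries zeroed) and
#'   `mask` (a `MaskIndex`: integer positions + original values)
#' @export
mask_nonzero <- function(x, fraction = 0.1, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  m <- unclass(x)
  nz <- which(m != 0)
  n_mask <- floor(fraction * length(nz))
  if (n_mask == 0L) {
    mask <- list(positions = integer(0), values = numeric(0), dim = dim(m))
    class(mask) <- "MaskIndex"
    return(list(masked = x, mask = mask))
  }
  pos <- with_seed(seed, sort(sample(nz, n_mask)))
  mask <- list(positions = pos, values = m[pos], dim = dim(m))
  class(mask) <- "MaskIndex"
  m[pos] <- 0
  masked <- if (inherits(x, "ExpressionMatrix")) {
    expression_matrix(m, labels = cell_labels(x))
  } else m
  list(masked = masked, mask = mask)
}

#' Restore masked originals
#' @param masked matrix produced by [mask_nonzero()]
#' @param mask the corresponding `MaskIndex`
#' @return matrix equal to the pre-masking input
#' @export
unmask <- function(masked, mask) {
  m <- unclass(masked)
  m[mask$positions] <- mask$values
  if (inherits(masked, "ExpressionMatrix")) {
    expression_matrix(m, labels = cell_labels(masked))
  } else m
}

check_graph_conformable <- function(g, x) {
  if (!inherits(g, "CellGraph")) stop("g must be a CellGraph")
  if (nrow(g$normalized) != nrow(x)) {
    stop("graph has ", nrow(g$normalized), " cells but matrix has ",
         nrow(x), " rows")
  }
}

#' One-layer graph-convolutional encoder
#'
#' `H = ReLU(Atilde X W1)`: neighbourhood-averaged features projected to
#' the latent width.
#'
#' @param g `CellGraph` carrying the normalized adjacency
#' @param x cells x genes matrix
#' @param w1 genes x d weight matrix
#' @return cells x d non-negative matrix
#' @export
gcn_encode <- function(g, x, w1) {
  check_graph_conformable(g, x)
  if (ncol(x) != nrow(w1)) {
    stop("matrix has ", ncol(x), " genes but W1 expects ", nrow(w1))
  }
  relu(g$normalized %*% unclass(x) %*% w1)
}

#' One-layer graph-convolutional decoder
#'
#' `Xrecon = ReLU(Atilde H W2)`: same propagation rule as the encoder,
#' mapping the latent representation back to gene space.
#'
#' @param g `CellGraph`
#' @param h cells x d latent matrix
#' @param w2 d x genes weight matrix
#' @return cells x genes non-negative reconstruction
#' @export
gcn_decode <- function(g, h, w2) {
  check_graph_conformable(g, h)
  if (ncol(h) != nrow(w2)) {
    stop("latent width ", ncol(h), " but W2 expects ", nrow(w2))
  }
  relu(g$normalized %*% h %*% w2)
}

#' Reconstruction loss restricted to masked entries
#'
#' The Euclidean norm of the difference between original and
#' reconstructed values over the masked positions only; entries outside
#' the mask contribute nothing, so the auto-encoder is supervised purely
#' by its ability to recover values it never saw.
#'
#' @param x_orig matrix holding the original (pre-masking) values
#' @param x_recon reconstructed matrix of the same shape
#' @param mask a `MaskIndex`
#' @return non-negative scalar
#' @export
masked_loss <- function(x_orig, x_recon, mask) {
  if (!length(mask$positions)) stop("empty mask: nothing to supervise")
  sqrt(sum((unclass(x_orig)[mask$positions] -
              unclass(x_recon)[mask$positions])^2))
}

#' Train a masked graph-convolutional auto-encoder for one view
#'
#' Masks a fraction of the non-zero entries of the normalized expression
#' matrix, then trains the one-layer GCN encoder/decoder pair to recover
#' the masked values, minimizing the masked Euclidean loss with
#' full-batch Adam. After training, the returned embedding `H` is
#' recomputed on the unmasked matrix — the denoised representation
#' carried forward by the rest of the pipeline.
#'
#' @param xhat normalized `ExpressionMatrix` (cells x genes)
#' @param g `CellGraph` for the same cells, same order
#' @param latent_dim embedding width `d` (default 64)
#' @param mask_fraction fraction of non-zero entries masked (default 0.1)
#' @param epochs training epochs (default 200)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed seed for mask and weight init
#' @param view_name label stored on the result
#' @param init optional warm start: a list (or `ViewEmbedding`) carrying
#'   `W1` and `W2` to continue training from instead of fresh init
#' @return a `ViewEmbedding`: list with `H`, `W1`, `W2`, `view_name`,
#'   `latent_dim`, `loss_history`
#' @export
train_autoencoder <- function(xhat, g, latent_dim = 64L, mask_fraction = 0.1,
                              epochs = 200L, lr = 1e-3, seed = 1L,
                              view_name = "view", init = NULL) {
  check_graph_conformable(g, xhat)
  M <- ncol(xhat)
  d <- as.integer(latent_dim)
  mk <- mask_nonzero(xhat, mask_fraction, seed = seed)
  if (!length(mk$mask$positions)) {
    stop("no entries were masked; increase mask_fraction or check the data")
  }
  xm <- unclass(mk$masked)
  targets <- mk$mask$values
  pos <- mk$mask$positions
  atil <- g$normalized

  params <- if (is.null(init)) {
    with_seed(seed + 1L, list(W1 = init_weights(M, d),
                              W2 = init_weights(d, M)))
  } else {
    stopifnot(all(dim(init$W1) == c(M, d)), all(dim(init$W2) == c(d, M)))
    list(W1 = init$W1, W2 = init$W2)
  }
  opt <- adam_init(params, lr = lr)
  axm <- atil %*% xm                      # fixed over epochs
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    z1 <- axm %*% params$W1
    h <- relu(z1)
    ah <- atil %*% h
    z2 <- ah %*% params$W2
    xr <- relu(z2)
    resid <- xr[pos] - targets
    loss <- sqrt(sum(resid^2))
    if (!is.finite(loss)) {
      stop("non-finite auto-encoder loss at epoch ", ep,
           " (last finite: ", if (ep > 1) loss_history[ep - 1] else NA, ")")
    }
    loss_history[ep] <- loss
    # d loss / d xr is supported on the mask only
    dxr <- matrix(0, nrow(xm), ncol(xm))
    if (loss > 0) dxr[pos] <- resid / loss
    g2 <- dxr * (z2 > 0)
    dW2 <- crossprod(ah, g2)
    dh <- (atil %*% g2) %*% t(params$W2)
    g1 <- dh * (z1 > 0)
    dW1 <- crossprod(axm, g1)
    upd <- adam_step(opt, params, list(W1 = dW1, W2 = dW2))
    opt <- upd$state
    params <- upd$params
  }
  H <- relu((atil %*% unclass(xhat)) %*% params$W1)
  rownames(H) <- rownames(xhat)
  structure(list(H = H, W1 = params$W1, W2 = params$W2,
                 view_name = view_name, latent_dim = d,
                 loss_history = loss_history),
            class = "ViewEmbedding")
}

#' @export
print.ViewEmbedding <- function(x, ...) {
  cat(sprintf("ViewEmbedding '%s': %d cells x %d dims (final masked loss %.4g)\n",
              x$view_name, nrow(x$H), x$latent_dim,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Embed query cells with a trained encoder
#'
#' Applies the frozen encoder weights to the query data and its own
#' graph: `H_test = ReLU(Atilde_test Xhat_test W1)`. No parameters are
#' updated; the query never influences training.
#'
#' @param xhat_test normalized query matrix over the same gene columns
#'   the encoder was trained on
#' @param g_test `CellGraph` built from the query cells only
#' @param w1 trained encoder weights (genes x d)
#' @return cells x d embedding matrix
#' @export
embed_test <- function(xhat_test, g_test, w1) {
  gcn_encode(g_test, xhat_test, w1)
}
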