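# Multi-view latent subspace learning: find one common representation h
# per cell from which every per-view embedding can be reconstructed by an
# affine map, while a margin-based label loss pushes classes apart.

view_matrix <- function(v) {
  if (inherits(v, "ViewEmbedding")) v$H else as.matrix(v)
}

check_views_aligned <- function(views) {
  hs <- lapply(views, view_matrix)
  ns <- vapply(hs, nrow, 1L)
  if (length(unique(ns)) != 1L) {
    stop("views disagree on cell count: ", paste(ns, collapse = ", "))
  }
  hs
}

#' Multi-view reconstruction loss
#'
#' `l_r = sum_i sum_v || f_v(h_i) - H_i^v ||_2` where each `f_v` is the
#' affine map `h W_v + b_v` from the shared subspace back to view `v`'s
#' embedding space. Zero iff every mapping reproduces every view row.
#'
#' @param state a `MultiviewState` (or list with `h` and `thetas`)
#' @param views list of `ViewEmbedding` objects (or bare matrices),
#'   aligned on cell order
#' @return non-negative scalar
#' @export
view_reconstruction_loss <- function(state, views) {
  hs <- check_views_aligned(views)
  if (nrow(hs[[1L]]) != nrow(state$h)) {
    stop("state and views disagree on cell count")
  }
  total <- 0
  for (v in seq_along(hs)) {
    th <- state$thetas[[v]]
    resid <- state$h %*% th$W + rep(th$b, each = nrow(state$h)) - hs[[v]]
    total <- total + sum(sqrt(rowSums(resid^2)))
  }
  total
}

# Per-cell margin loss components shared by the loss and its gradient.
# For anchor i with class c_i, the loss is
#   max(0, max_{y != c_i} (1 + mean_{tau(y)} h^T h_i
#                            - mean_{tau(c_i) \ i} h^T h_i))
# (the y = c_i candidate contributes 0 because its two expectations
# coincide). Same-class means exclude the anchor; a singleton class
# falls back to including it.
margin_components <- function(h, labels, alphabet) {
  n <- nrow(h)
  ci <- match(labels, alphabet)
  if (anyNA(ci)) {
    stop("labels outside the alphabet: ",
         paste(unique(labels[is.na(ci)]), collapse = ", "))
  }
  C <- length(alphabet)
  Z <- matrix(0, n, C)
  Z[cbind(seq_len(n), ci)] <- 1
  n_c <- colSums(Z)
  S <- tcrossprod(h) %*% Z                      # S[i, c] = sum_{j in c} h_j^T h_i
  own_n <- n_c[ci] - 1
  own_sum <- S[cbind(seq_len(n), ci)] - rowSums(h^2)
  own_mean <- ifelse(own_n > 0, own_sum / own_n,
                     S[cbind(seq_len(n), ci)] / n_c[ci])
  term <- 1 + sweep(S, 2L, n_c, "/") - own_mean
  term[cbind(seq_len(n), ci)] <- 0
  best <- max.col(term, ties.method = "first")
  best_val <- term[cbind(seq_len(n), best)]
  loss_i <- pmax(0, best_val)
  list(loss_i = loss_i, best = best, ci = ci, Z = Z, n_c = n_c,
       own_n = own_n)
}

#' Margin-based misclassification loss
#'
#' For each labeled cell the loss penalizes any class whose mean inner
#' product with the cell's latent vector comes within a margin of 1 of
#' the cell's own-class mean; it is zero once same-class similarity
#' exceeds other-class similarity by the margin for every cell. Returns
#' the sum over cells.
#'
#' @param state `MultiviewState` (or list with `h` and `label_alphabet`)
#' @param labels character vector, one label per cell
#' @return non-negative scalar
#' @export
misclassification_loss <- function(state, labels) {
  alphabet <- state$label_alphabet
  if (is.null(alphabet)) alphabet <- sort(unique(labels))
  sum(margin_components(state$h, labels, alphabet)$loss_i)
}

# Reconstruction residual direction per view: list of U_v (unit residual
# rows) and the summed loss.
recon_residuals <- function(h, thetas, hs) {
  us <- vector("list", length(hs))
  total <- 0
  for (v in seq_along(hs)) {
    th <- thetas[[v]]
    resid <- h %*% th$W + rep(th$b, each = nrow(h)) - hs[[v]]
    nv <- sqrt(rowSums(resid^2))
    total <- total + sum(nv)
    scale <- ifelse(nv > 0, 1 / nv, 0)
    us[[v]] <- resid * scale
  }
  list(us = us, loss = total)
}

#' Fit the shared latent subspace on labeled training views
#'
#' Alternating gradient descent on
#' `L_m = (l_r + lambda * l_c) / N`: each epoch first updates every
#' view's affine mapping parameters against the reconstruction loss,
#' then updates the latent rows against the full objective, with class
#' means of the margin loss recomputed once per epoch. Stops when the
#' misclassification loss is converged (relative change below `tol`
#' across a 10-epoch window) or at `epochs`.
#'
#' @param views list of `ViewEmbedding` objects sharing cell order
#' @param labels per-cell class labels
#' @param subspace_dim shared latent width `d_s` (default 32)
#' @param lambda weight of the label loss (default 1)
#' @param lr learning rate `alpha` (default 1e-2)
#' @param epochs maximum training epochs (default 300)
#' @param tol relative convergence tolerance on the label loss
#' @param seed RNG seed for initialization
#' @param init_thetas optional warm start for the view mappings (a list
#'   of `list(W, b)` as stored on a fitted `MultiviewState`); `h` is
#'   always initialized fresh since latent rows are per-cell
#' @param label_alphabet optional fixed class alphabet (defaults to the
#'   sorted unique labels); labels outside it are an error
#' @return a `MultiviewState`: list with `h`, `thetas`, `lambda`, `lr`,
#'   `label_alphabet`, `subspace_dim`, `loss_history`, `epochs_run`
#' @export
fit_multiview <- function(views, labels, subspace_dim = 32L, lambda = 1,
                          lr = 1e-2, epochs = 300L, tol = 1e-4, seed = 1L,
                          init_thetas = NULL, label_alphabet = NULL) {
  if (!length(views)) stop("need at least one view")
  hs <- check_views_aligned(views)
  n <- nrow(hs[[1L]])
  if (length(labels) != n) stop("labels length != cell count")
  if (lambda < 0) stop("lambda must be positive")
  d_s <- as.integer(subspace_dim)
  labels <- as.character(labels)
  alphabet <- if (is.null(label_alphabet)) sort(unique(labels))
              else label_alphabet
  if (!all(labels %in% alphabet)) {
    stop("labels outside the alphabet: ",
         paste(setdiff(unique(labels), alphabet), collapse = ", "))
  }

  init <- with_seed(seed, {
    thetas <- if (is.null(init_thetas)) {
      lapply(hs, function(hv) {
        list(W = init_weights(d_s, ncol(hv)), b = numeric(ncol(hv)))
      })
    } else init_thetas
    list(thetas = thetas, h = matrix(stats::rnorm(n * d_s, sd = 0.1), n, d_s))
  })
  thetas <- init$thetas
  h <- init$h

  hist_lr <- hist_lc <- hist_lm <- numeric(epochs)
  ep_run <- 0L
  for (ep in seq_len(epochs)) {
    # theta step (reconstruction loss only), one view at a time
    for (v in seq_along(hs)) {
      th <- thetas[[v]]
      resid <- h %*% th$W + rep(th$b, each = n) - hs[[v]]
      nv <- sqrt(rowSums(resid^2))
      u <- resid * ifelse(nv > 0, 1 / nv, 0)
      thetas[[v]]$W <- th$W - (lr / n) * crossprod(h, u)
      thetas[[v]]$b <- th$b - (lr / n) * colSums(u)
    }
    # h step against the full objective, with updated thetas
    rr <- recon_residuals(h, thetas, hs)
    dh <- Reduce(`+`, lapply(seq_along(hs), function(v) {
      rr$us[[v]] %*% t(thetas[[v]]$W)
    }))
    mc <- margin_components(h, labels, alphabet)
    lc <- sum(mc$loss_i)
    if (lambda > 0) {
      mu_c <- crossprod(mc$Z, h) / mc$n_c        # C x d_s class means
      active <- which(mc$loss_i > 0 & mc$best != mc$ci)
      if (length(active)) {
        # own-class mean excluding the anchor (fallback: class mean)
        own_mu <- (mu_c[mc$ci[active], , drop = FALSE] *
                     mc$n_c[mc$ci[active]] - h[active, , drop = FALSE])
        own_n <- mc$n_c[mc$ci[active]] - 1
        fallback <- own_n == 0
        own_mu <- own_mu / ifelse(own_n > 0, own_n, 1)
        if (any(fallback)) {
          own_mu[fallback, ] <- mu_c[mc$ci[active][fallback], , drop = FALSE]
        }
        dh[active, ] <- dh[active, , drop = FALSE] + lambda *
          (mu_c[mc$best[active], , drop = FALSE] - own_mu)
      }
    }
    h <- h - (lr / n) * dh
    if (!all(is.finite(h))) {
      stop("multi-view optimization diverged at epoch ", ep,
           " (last objective ", if (ep > 1) hist_lm[ep - 1] else NA, ")")
    }
    hist_lr[ep] <- rr$loss
    hist_lc[ep] <- lc
    hist_lm[ep] <- (rr$loss + lambda * lc) / n
    ep_run <- ep
    if (ep > 10L) {
      ref <- hist_lc[ep - 10L]
      if (abs(hist_lc[ep] - ref) < tol * max(abs(ref), 1e-12)) break
    }
  }
  rownames(h) <- rownames(hs[[1L]])
  structure(list(
    h = h, thetas = thetas, lambda = lambda, lr = lr,
    label_alphabet = alphabet, subspace_dim = d_s,
    loss_history = data.frame(epoch = seq_len(ep_run),
                              recon = hist_lr[seq_len(ep_run)],
                              margin = hist_lc[seq_len(ep_run)],
                              objective = hist_lm[seq_len(ep_run)]),
    epochs_run = ep_run
  ), class = "MultiviewState")
}

#' @export
print.MultiviewState <- function(x, ...) {
  cat(sprintf(paste0("MultiviewState: %d cells x %d latent dims, %d views, ",
                     "%d classes (%d epochs)\n"),
              nrow(x$h), x$subspace_dim, length(x$thetas),
              length(x$label_alphabet), x$epochs_run))
  invisible(x)
}

#' Infer latent representations for query cells
#'
#' The view mappings learned in training are frozen; each query cell's
#' latent vector is optimized against the reconstruction loss alone (no
#' label information exists for queries). Initialization solves the
#' joint ridge least-squares problem across all views,
#' `argmin_h sum_v ||h W_v - (H_v - b_v)||^2 + mu ||h||^2` with a small
#' `mu` tied to the spectrum of `sum_v W_v W_v^T`, which lands each cell
#' in the subspace region the trained mappings actually reconstruct
#' from; `init = "random"` gives seeded Gaussian init instead.
#'
#' @param views_test list of query `ViewEmbedding`s, same view count and
#'   order as training
#' @param state trained `MultiviewState`
#' @param epochs gradient steps (default 100)
#' @param init `"projection"` or `"random"`
#' @param seed seed for random init
#' @return cells x `d_s` latent matrix with attribute
#'   `"loss_history"` (per-epoch reconstruction loss)
#' @export
infer_latent_test <- function(views_test, state, epochs = 100L,
                              init = c("projection", "random"), seed = 1L) {
  init <- match.arg(init)
  if (length(views_test) != length(state$thetas)) {
    stop("view count mismatch: model has ", length(state$thetas),
         " views, query supplies ", length(views_test))
  }
  hs <- check_views_aligned(views_test)
  n <- nrow(hs[[1L]])
  d_s <- state$subspace_dim
  h <- if (init == "projection") {
    gram <- matrix(0, d_s, d_s)
    rhs <- matrix(0, n, d_s)
    for (v in seq_along(hs)) {
      th <- state$thetas[[v]]
      gram <- gram + th$W %*% t(th$W)
      rhs <- rhs + (hs[[v]] - rep(th$b, each = n)) %*% t(th$W)
    }
    mu <- 1e-3 * max(eigen(gram, symmetric = TRUE, only.values = TRUE)$values,
                     .Machine$double.eps)
    t(solve(gram + mu * diag(d_s), t(rhs)))
  } else {
    with_seed(seed, matrix(stats::rnorm(n * d_s, sd = 0.1), n, d_s))
  }
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    rr <- recon_residuals(h, state$thetas, hs)
    dh <- Reduce(`+`, lapply(seq_along(hs), function(v) {
      rr$us[[v]] %*% t(state$thetas[[v]]$W)
    }))
    h <- h - (state$lr / n) * dh
    hist[ep] <- rr$loss
  }
  rownames(h) <- rownames(hs[[1L]])
  attr(h, "loss_history") <- hist
  h
}
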