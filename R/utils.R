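# Internal numerical helpers shared across modules.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax with max-subtraction for numerical stability
#' @param z numeric matrix of logits (rows = observations)
#' @return matrix of the same shape; every row sums to 1
#' @keywords internal
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Moore-Penrose pseudo-inverse via SVD; tolerance relative to largest
# singular value (same convention as MASS::ginv).
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1L]
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Symmetric-uniform weight init scaled by fan-in/fan-out (Glorot).
init_weights <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Adam optimizer state for a list of parameter matrices.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  corr1 <- 1 - state$beta1^state$t
  corr2 <- 1 - state$beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- state$beta1 * state$m[[i]] + (1 - state$beta1) * grads[[i]]
    state$v[[i]] <- state$beta2 * state$v[[i]] + (1 - state$beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / corr1
    vhat <- state$v[[i]] / corr2
    params[[i]] <- params[[i]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

#' Fan a root seed out into deterministic per-stage seeds
#'
#' Every stochastic stage of the pipeline draws its own seed from the root
#' seed so that stages can be re-run or reordered without perturbing each
#' other's random streams. Seeds stay below 2^31 - 1.
#'
#' @param root_seed single integer root seed
#' @param n number of stage seeds needed
#' @return integer vector of length `n`
#' @keywords internal
fan_out_seeds <- function(root_seed, n) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

# Run expr with a local RNG state seeded at `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  expr
}

# Smoothed (windowed mean) loss series, used by the convergence contracts.
smooth_series <- function(x, window = 10L) {
  n <- length(x)
  if (n < window) {
    return(mean(x))
  }
  stats::filter(x, rep(1 / window, window), sides = 1)[window:n]
}
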