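make_state <- function(h, thetas, alphabet = NULL, lambda = 1, lr = 1) {
  structure(list(h = h, thetas = thetas, lambda = lambda, lr = lr,
                 label_alphabet = alphabet, subspace_dim = ncol(h)),
            class = "MultiviewState")
}

test_that("reconstruction loss is zero iff mappings reproduce every view", {
  set.seed(40)
  h <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2)
  b <- c(0.5, -1)
  view_exact <- h %*% W + rep(b, each = 4)
  st <- make_state(h, list(list(W = W, b = b)))
  expect_equal(view_reconstruction_loss(st, list(view_exact)), 0)

  # single view, single cell, residual (3, 4) -> 5
  st1 <- make_state(matrix(0, 1, 3),
                    list(list(W = matrix(0, 3, 2), b = c(0, 0))))
  expect_equal(view_reconstruction_loss(st1, list(matrix(c(-3, -4), 1))), 5)

  # adding a view can only increase the loss
  st2 <- make_state(h, list(list(W = W, b = b), list(W = W, b = b)))
  noisy <- view_exact + 1
  expect_gte(view_reconstruction_loss(st2, list(view_exact, noisy)),
             view_reconstruction_loss(st, list(view_exact)))
  expect_error(view_reconstruction_loss(st, list(view_exact[1:2, ])),
               "cell count")
})

test_that("reconstruction loss is invariant to simultaneous cell permutation", {
  set.seed(41)
  h <- matrix(rnorm(30), 10, 3)
  th <- list(list(W = matrix(rnorm(12), 3, 4), b = rnorm(4)))
  v <- matrix(rnorm(40), 10, 4)
  st <- make_state(h, th)
  perm <- sample(10)
  stp <- make_state(h[perm, ], th)
  expect_equal(view_reconstruction_loss(stp, list(v[perm, ])),
               view_reconstruction_loss(st, list(v)))
})

test_that("margin loss equals the explicit brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    h <- matrix(rnorm(10 * 4), 10, 4)
    labels <- sample(c("a", "b", "c"), 10, replace = TRUE)
    while (length(unique(labels)) < 2) {
      labels <- sample(c("a", "b", "c"), 10, replace = TRUE)
    }
    st <- make_state(h, list(), alphabet = sort(unique(labels)))
    expect_equal(misclassification_loss(st, labels),
                 margin_oracle(h, labels), tolerance = 1e-10)
  }
})

test_that("margin loss edge cases: one class, zero latent, wide separation", {
  h <- matrix(rnorm(12), 4, 3)
  st <- make_state(h, list(), alphabet = "only")
  expect_equal(misclassification_loss(st, rep("only", 4)), 0)

  h0 <- matrix(0, 6, 3)
  st0 <- make_state(h0, list(), alphabet = c("a", "b"))
  expect_equal(misclassification_loss(st0, rep(c("a", "b"), 3)), 6)

  # two tight clusters far apart: same-class inner products dominate by
  # far more than the unit margin
  hsep <- rbind(matrix(5, 2, 2) + 0.01, matrix(-5, 2, 2) - 0.01)
  stsep <- make_state(hsep, list(), alphabet = c("a", "b"))
  expect_equal(misclassification_loss(stsep, c("a", "a", "b", "b")), 0)

  expect_error(misclassification_loss(st0, rep("zzz", 6)), "alphabet")
})

test_that("subspace fitting converges and handles a single view", {
  fit <- small_fit()
  lh <- fit$mv$loss_history
  expect_lt(utils::tail(lh$objective, 1), lh$objective[1])
  expect_lt(utils::tail(lh$margin, 1), lh$margin[1])

  sim <- small_sim()
  one <- scpml(sim$expression, sim$pathways[[1]], control = small_ctrl(),
               seed = 5)
  expect_s3_class(one, "scpml")
  expect_length(one$views, 1L)
  expect_gte(one$training_accuracy, 0.9)
})

test_that("with lambda = 0 the fit ignores labels entirely", {
  set.seed(43)
  H <- matrix(rnorm(20 * 6), 20, 6)
  labels <- rep(c("a", "b"), 10)
  f1 <- fit_multiview(list(H), labels, subspace_dim = 3, lambda = 0,
                      epochs = 40, seed = 7)
  f2 <- fit_multiview(list(H), sample(labels), subspace_dim = 3, lambda = 0,
                      epochs = 40, seed = 7)
  expect_identical(f1$h, f2$h)
  expect_identical(f1$thetas, f2$thetas)
})

test_that("duplicated twin views behave like one view at doubled recon weight", {
  set.seed(44)
  n <- 40
  H <- matrix(rnorm(n * 12), n, 12) + rep(c(0, 3), each = n / 2)
  labels <- rep(c("a", "b"), each = n / 2)
  th0 <- list(W = scpml:::init_weights(8, 12), b = numeric(12))
  dup <- fit_multiview(list(H, H), labels, subspace_dim = 8, lambda = 1,
                       lr = 1, epochs = 150, tol = 0, seed = 2,
                       init_thetas = list(th0, th0))
  # identical inputs and init keep the two mappings bitwise in lockstep
  expect_identical(dup$thetas[[1]], dup$thetas[[2]])
  single <- fit_multiview(list(H), labels, subspace_dim = 8, lambda = 0.5,
                          lr = 2, epochs = 150, tol = 0, seed = 2,
                          init_thetas = list(th0))
  expect_gt(stats::cor(c(dup$h), c(single$h)), 0.9)
})

test_that("query latent inference freezes the mappings and reduces loss", {
  fit <- bench_fit()
  pair <- bench_pair()
  ctrl <- fit$control
  xq <- scpml:::prepare_features(pair$test, fit$hvgs, ctrl)
  vt <- lapply(seq_along(fit$views), function(v) {
    g <- scpml:::build_view_graph(pair$test, fit$pathways[[v]], ctrl)
    embed_test(xq, g, fit$views[[v]]$W1) / fit$view_scales[v]
  })
  before <- serialize(fit$mv$thetas, NULL)
  h <- infer_latent_test(vt, fit$mv, epochs = 50)
  expect_identical(serialize(fit$mv$thetas, NULL), before)
  lh <- attr(h, "loss_history")
  expect_lt(mean(utils::tail(lh, 5)), mean(utils::head(lh, 5)))
  expect_error(infer_latent_test(vt[1], fit$mv), "view count")
})

test_that("inference on the training views reproduces training predictions", {
  fit <- small_fit()
  sim <- small_sim()
  pred_train <- predict_cells(fit$mv$h, fit$classifier, threshold = 1e-12)
  pred_inferred <- predict(fit, sim$expression, threshold = 1e-12)
  agreement <- mean(pred_train$label == pred_inferred$label)
  expect_gte(agreement, 0.95)
})
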