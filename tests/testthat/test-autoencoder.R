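test_that("masking zeroes the sampled entries and is exactly reversible", {
  set.seed(30)
  x <- expression_matrix(matrix(rpois(50, 2), 5, 10))
  nz <- sum(unclass(x) != 0)
  mk <- mask_nonzero(x, 0.2, seed = 1)
  expect_length(mk$mask$positions, floor(0.2 * nz))
  expect_true(all(unclass(mk$masked)[mk$mask$positions] == 0))
  expect_identical(unclass(unmask(mk$masked, mk$mask)), unclass(x))

  same <- mask_nonzero(x, 0.2, seed = 1)
  expect_identical(same$mask$positions, mk$mask$positions)

  none <- mask_nonzero(x, 0, seed = 1)
  expect_identical(unclass(none$masked), unclass(x))
  expect_length(none$mask$positions, 0L)

  zeros <- expression_matrix(matrix(0, 3, 3))
  mz <- mask_nonzero(zeros, 0.5, seed = 1)
  expect_length(mz$mask$positions, 0L)

  expect_error(mask_nonzero(x, 1), "fraction")
})

test_that("exactly 2 of 10 non-zeros are masked at fraction 0.2", {
  m <- matrix(0, 4, 5)
  m[1:10] <- 1:10
  x <- expression_matrix(m)
  mk <- mask_nonzero(x, 0.2, seed = 9)
  expect_length(mk$mask$positions, 2L)
  expect_equal(sum(unclass(mk$masked) == 0), 12)  # 10 zeros + 2 masked
})

test_that("GCN propagation matches the dense linear-algebra oracle", {
  set.seed(31)
  n <- 15; M <- 12; d <- 4
  s <- similarity_matrix(matrix(runif(n * 3), n, 3))
  g <- mnn_graph(s, 4)
  x <- matrix(rpois(n * M, 3), n, M)
  w1 <- matrix(rnorm(M * d), M, d)
  w2 <- matrix(rnorm(d * M), d, M)
  h <- gcn_encode(g, x, w1)
  h_oracle <- pmax(g$normalized %*% (x %*% w1), 0)   # different association
  expect_equal(h, h_oracle, tolerance = 1e-10)
  expect_true(all(h >= 0))
  r <- gcn_decode(g, h, w2)
  expect_equal(r, pmax(g$normalized %*% (h %*% w2), 0), tolerance = 1e-10)
  expect_true(all(gcn_decode(g, h * 0, w2) == 0))
  expect_error(gcn_encode(g, x, w2), "W1 expects")
})

test_that("an isolated cell propagates through identity weights as ReLU", {
  g1 <- cell_graph(matrix(0, 1, 1))
  x <- matrix(c(-2, 0, 3), 1)
  expect_equal(gcn_encode(g1, x, diag(3)), matrix(c(0, 0, 3), 1))
})

test_that("the masked loss sees only masked positions", {
  x <- matrix(c(3, 1, 0, 2), 2, 2)
  mask <- structure(list(positions = 1L, values = 3, dim = c(2L, 2L)),
                    class = "MaskIndex")
  recon0 <- matrix(0, 2, 2)
  expect_equal(masked_loss(x, recon0, mask), 3)
  expect_equal(masked_loss(x, x, mask), 0)
  recon_perturbed <- recon0
  recon_perturbed[2:4] <- 99
  expect_equal(masked_loss(x, recon_perturbed, mask), 3)
  empty <- structure(list(positions = integer(0), values = numeric(0)),
                     class = "MaskIndex")
  expect_error(masked_loss(x, recon0, empty), "empty mask")
})

test_that("auto-encoder training reduces the masked loss deterministically", {
  sim <- small_sim()
  ctrl <- small_ctrl()
  x <- median_normalize(sim$expression)
  g <- scpml:::build_view_graph(sim$expression, sim$pathways[[1]], ctrl)
  ve <- train_autoencoder(x, g, latent_dim = 16, epochs = 60, seed = 3)
  expect_lt(mean(utils::tail(ve$loss_history, 10)),
            mean(utils::head(ve$loss_history, 10)))
  ve2 <- train_autoencoder(x, g, latent_dim = 16, epochs = 60, seed = 3)
  expect_identical(ve$W1, ve2$W1)
  expect_identical(ve$H, ve2$H)
})

test_that("with no bottleneck the masked loss shrinks well below its start", {
  set.seed(33)
  x <- expression_matrix(matrix(rpois(8 * 10, 5), 8, 10))
  s <- similarity_matrix(matrix(runif(24), 8, 3))
  g <- mnn_graph(s, 3)
  ve <- train_autoencoder(x, g, latent_dim = 10, mask_fraction = 0.2,
                          epochs = 2000, lr = 1e-2, seed = 1)
  expect_lt(utils::tail(ve$loss_history, 1), 0.5 * ve$loss_history[1])
})

test_that("training never reads the masked originals outside the loss", {
  set.seed(34)
  x <- expression_matrix(matrix(rpois(60, 4) + 1, 6, 10))
  mk <- mask_nonzero(x, 0.3, seed = 2)
  # corrupt the original values at the masked positions; the masked
  # input matrix (what the encoder consumes) is unchanged
  corrupted <- unclass(x)
  corrupted[mk$mask$positions] <- 1e6
  mk2 <- mask_nonzero(expression_matrix(corrupted), 0.3, seed = 2)
  expect_identical(unclass(mk2$masked), unclass(mk$masked))
  g <- mnn_graph(similarity_matrix(matrix(runif(18), 6, 3)), 2)
  w1 <- matrix(rnorm(10 * 3), 10, 3)
  expect_identical(gcn_encode(g, unclass(mk$masked), w1),
                   gcn_encode(g, unclass(mk2$masked), w1))
})

test_that("query embedding reuses frozen weights and is permutation-equivariant", {
  sim <- small_sim()
  ctrl <- small_ctrl()
  x <- median_normalize(sim$expression)
  g <- scpml:::build_view_graph(sim$expression, sim$pathways[[1]], ctrl)
  ve <- train_autoencoder(x, g, latent_dim = 8, epochs = 30, seed = 4)
  h_same <- embed_test(x, g, ve$W1)
  expect_equal(h_same, ve$H)

  perm <- sample(nrow(x))
  xp <- unclass(x)[perm, ]
  gp <- cell_graph(g$adjacency[perm, perm])
  hp <- embed_test(xp, gp, ve$W1)
  expect_equal(unname(hp), unname(h_same[perm, ]), tolerance = 1e-12)

  expect_error(embed_test(unclass(x)[, 1:5], g, ve$W1), "W1 expects")
})

test_that("embeddings preserve class structure on separated synthetic types", {
  fit <- small_fit()
  labels <- cell_labels(small_sim()$expression)
  h <- fit$views[[1]]$H
  hn <- h / pmax(sqrt(rowSums(h^2)), 1e-12)
  cs <- tcrossprod(hn)
  same <- outer(labels, labels, "==")
  diag(cs) <- NA
  expect_gt(mean(cs[same], na.rm = TRUE), mean(cs[!same], na.rm = TRUE))
})
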