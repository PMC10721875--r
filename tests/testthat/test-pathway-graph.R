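test_that("pathway scores match hand-computed recovery-curve areas", {
  x <- expression_matrix(matrix(c(10, 5, 2, 1), 1), gene_ids = paste0("g", 1:4))
  p <- pathway_collection(list(P = c("g1", "g2")))
  q <- score_pathways(x, p, max_rank_fraction = 1, min_overlap = 1)
  # cumulative hits per rank (1,2,2,2): area 7 of a maximal 2*4 = 8
  expect_equal(unname(unclass(q)[1, 1]), 7 / 8)
})

test_that("scores equal the brute-force step-curve oracle on a seeded instance", {
  set.seed(17)
  x <- expression_matrix(matrix(rpois(20 * 50, 5), 20, 50))
  sets <- lapply(1:5, function(i) sample(colnames(x), sample(6:15, 1)))
  names(sets) <- paste0("P", 1:5)
  p <- pathway_collection(sets)
  q <- score_pathways(x, p, max_rank_fraction = 1, min_overlap = 1)
  for (i in seq_len(nrow(x))) {
    for (j in seq_along(sets)) {
      expect_equal(unclass(q)[i, j],
                   auc_oracle(unclass(x)[i, ],
                              which(colnames(x) %in% sets[[j]]), 50L),
                   tolerance = 1e-10)
    }
  }
  # the same holds under a restricted scoring window
  q2 <- score_pathways(x, p, max_rank_fraction = 0.2, min_overlap = 1)
  w <- ceiling(0.2 * 50)
  for (i in seq_len(nrow(x))) {
    expect_equal(unclass(q2)[i, 3],
                 auc_oracle(unclass(x)[i, ],
                            which(colnames(x) %in% sets[[3]]), w),
                 tolerance = 1e-10)
  }
})

test_that("scores are rank-based: invariant under strictly monotone transforms", {
  set.seed(18)
  x <- expression_matrix(matrix(rpois(10 * 30, 4), 10, 30))
  p <- pathway_collection(list(A = colnames(x)[1:8], B = colnames(x)[15:25]))
  q1 <- score_pathways(x, p, max_rank_fraction = 0.3)
  xt <- expression_matrix(3 * unclass(x)^2 + 1)
  q2 <- score_pathways(xt, p, max_rank_fraction = 0.3)
  expect_equal(unclass(q1), unclass(q2))
})

test_that("a pathway with no member in the scored window scores zero", {
  # pathway genes carry the lowest counts; window covers the top half only
  x <- expression_matrix(matrix(c(9, 8, 7, 6, 0, 0), 1),
                         gene_ids = paste0("g", 1:6))
  p <- pathway_collection(list(P = c("g5", "g6")))
  q <- score_pathways(x, p, max_rank_fraction = 0.5, min_overlap = 1)
  expect_equal(unname(unclass(q)[1, 1]), 0)
})

test_that("pathways under the overlap floor are dropped; none surviving errors", {
  x <- expression_matrix(matrix(rpois(40, 4), 4, 10))
  p <- pathway_collection(list(big = colnames(x)[1:6],
                               tiny = colnames(x)[1:2]))
  expect_message(q <- score_pathways(x, p, min_overlap = 5),
                 "dropping 1 pathway")
  expect_identical(colnames(q), "big")
  alltiny <- pathway_collection(list(t1 = colnames(x)[1:2]))
  expect_error(suppressMessages(score_pathways(x, alltiny, min_overlap = 5)),
               "no pathway survives")
})

test_that("similarity follows 1/(1+distance) with unit diagonal and symmetry", {
  q <- rbind(c(0, 0), c(3, 4), c(0, 0))
  s <- similarity_matrix(q)
  expect_equal(s[1, 3], 1)        # identical score rows
  expect_equal(s[1, 2], 1 / 6)    # distance 5
  expect_identical(unclass(s), t(unclass(s)))
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_error(similarity_matrix(rbind(c(1, NA))), "non-finite")
})

test_that("similarity decreases monotonically with score distance", {
  base <- c(0.2, 0.4)
  dists <- seq(0.1, 2, length.out = 10)
  sims <- vapply(dists, function(d) {
    similarity_matrix(rbind(base, base + c(d, 0)))[1, 2]
  }, 1)
  expect_true(all(diff(sims) < 0))
})

test_that("MNN graph keeps only reciprocated neighbourhoods", {
  # cells 1-2 mutually top-1; cell 3's top-1 (cell 2) is not reciprocated
  s <- matrix(c(1, .9, .1,
                .9, 1, .3,
                .1, .3, 1), 3, 3, byrow = TRUE)
  g <- mnn_graph(structure(s, class = c("SimilarityMatrix", "matrix", "array")),
                 k = 1)
  expect_equal(unname(g$adjacency),
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3))
})

test_that("MNN graph equals the exhaustive-sort oracle and saturates at k = N-1", {
  set.seed(19)
  q <- matrix(runif(40 * 6), 40, 6)
  s <- similarity_matrix(q)
  for (k in c(1, 5, 15)) {
    g <- mnn_graph(s, k)
    expect_identical(unname(g$adjacency), mnn_oracle(unclass(s), k))
    expect_identical(g$adjacency, t(g$adjacency))
    expect_equal(unname(diag(g$adjacency)), rep(0, 40))
  }
  g_full <- mnn_graph(s, 39)
  expect_equal(unname(g_full$adjacency), 1 - diag(40))
  expect_error(mnn_graph(s, 0), "k must")
  expect_error(mnn_graph(s, 40), "k must")
})

test_that("adjacency normalization matches closed forms and is spectrally bounded", {
  iso <- cell_graph(matrix(0, 1, 1))
  expect_equal(iso$normalized[1, 1], 1)

  pair <- cell_graph(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(pair$normalized), matrix(0.5, 2, 2))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  gs <- cell_graph(star)
  expect_equal(gs$normalized[1, 2], 1 / sqrt(4 * 2))

  set.seed(20)
  s <- similarity_matrix(matrix(runif(30 * 4), 30, 4))
  g <- mnn_graph(s, 6)
  ev <- eigen(g$normalized, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(ev), 1 + 1e-8)
})

test_that("graphs and scores export to edge lists, MTX and TSV", {
  s <- similarity_matrix(matrix(runif(12), 6, 2))
  g <- mnn_graph(s, 2)
  d <- withr::local_tempdir()
  write_graph(g, file.path(d, "edges.tsv"), "edgelist")
  edges <- utils::read.table(file.path(d, "edges.tsv"), header = TRUE)
  expect_equal(nrow(edges), sum(g$adjacency) / 2)
  write_graph(g, file.path(d, "adj.mtx"), "mtx")
  back <- as.matrix(Matrix::readMM(file.path(d, "adj.mtx"))) * 1
  expect_equal(unname(back), unname(g$adjacency))
  q <- score_pathways(expression_matrix(matrix(rpois(40, 5), 4, 10)),
                      pathway_collection(list(P = paste0("gene_", 1:6))),
                      max_rank_fraction = 1, min_overlap = 1)
  write_scores(q, file.path(d, "scores.tsv"))
  expect_equal(nrow(utils::read.table(file.path(d, "scores.tsv"),
                                      header = TRUE)), 4)
})
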