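# Shared fixtures and independent oracles. Heavy fits are computed once
# per test run and cached for every file that needs them.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache, inherits = FALSE)
}

# the 3-class, 2-view, 600-cell cross-batch benchmark
bench_pair <- function() {
  cached("bench_pair", simulate_query_pair(n_cells_per_class = 100, seed = 11))
}

bench_fit <- function() {
  cached("bench_fit",
         scpml(bench_pair()$train, bench_pair()$pathways, seed = 11))
}

# a lighter dataset + reduced-epoch settings for structural tests
small_sim <- function() {
  cached("small_sim",
         simulate_cells(n_cells_per_class = 25, n_genes = 200,
                        genes_per_pathway = 12, seed = 5))
}

small_ctrl <- function() {
  scpml_control(ae_epochs = 40, mv_epochs = 60, clf_epochs = 60,
                n_hvgs = 150)
}

small_fit <- function() {
  cached("small_fit",
         scpml(small_sim()$expression, small_sim()$pathways,
               control = small_ctrl(), seed = 5))
}

smoothed <- function(x, window = 10L) {
  as.numeric(stats::filter(x, rep(1 / window, window),
                           sides = 1))[window:length(x)]
}

expect_smoothly_decreasing <- function(x, slack = 0.03, window = 10L) {
  s <- smoothed(x, window)
  expect_true(all(diff(s) <= slack * pmax(abs(s[-length(s)]), 1e-12)))
  expect_lt(s[length(s)], s[1L])
}

# --- independent brute-force oracles -----------------------------------

# AUC by explicit step-curve enumeration over every rank of the window.
auc_oracle <- function(counts, member_idx, window) {
  ord <- order(-counts, seq_along(counts))
  hits_curve <- numeric(window)
  hits <- 0
  for (r in seq_len(window)) {
    if (ord[r] %in% member_idx) hits <- hits + 1
    hits_curve[r] <- hits
  }
  sum(hits_curve) / (length(member_idx) * window)
}

# MNN adjacency as the intersection of directed k-NN edge sets computed
# by exhaustive sorting.
mnn_oracle <- function(s, k) {
  n <- nrow(s)
  directed <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    others <- setdiff(seq_len(n), j)
    ranked <- others[order(-s[others, j], others)]
    directed[ranked[seq_len(k)], j] <- TRUE
  }
  (directed & t(directed)) * 1
}

# Margin loss by explicit loops over cells and candidate classes,
# following the declared semantics: the own-class candidate contributes
# zero; same-class means exclude the anchor; singleton classes fall
# back to including it.
margin_oracle <- function(h, labels, alphabet = sort(unique(labels))) {
  n <- nrow(h)
  total <- 0
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) own <- which(labels == labels[i])
    own_mean <- mean(h[own, , drop = FALSE] %*% h[i, ])
    best <- 0
    for (y in alphabet) {
      if (y == labels[i]) next
      members <- which(labels == y)
      if (!length(members)) next
      m_y <- mean(h[members, , drop = FALSE] %*% h[i, ])
      best <- max(best, 1 + m_y - own_mean)
    }
    total <- total + max(0, best)
  }
  total
}

# Small deterministic labeled matrix for preprocessing tests.
tiny_labeled <- function() {
  set.seed(42)
  m <- matrix(rpois(60, 8), nrow = 10)
  expression_matrix(m, gene_ids = paste0("g", 1:6),
                    cell_ids = paste0("c", 1:10),
                    labels = rep(c("x", "y"), each = 5))
}

# Query restricted to a random fraction of the genes (coverage stress).
subset_genes_fixture <- function(x, keep_fraction) {
  set.seed(99)
  keep <- sort(sample(ncol(x), ceiling(keep_fraction * ncol(x))))
  expression_matrix(unclass(x)[, keep, drop = FALSE],
                    labels = cell_labels(x))
}
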