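#' Score pathway activity per cell (rank-based AUC)
#'
#' For each cell, genes are ranked by decreasing expression (ties broken
#' by gene index for determinism, or randomly per cell when
#' `tie_break = "random"`). For a pathway with `k` member genes present
#' in the matrix, the recovery curve counts the members found within the
#' top `r` ranks; the score is the area under that step curve over the
#' window of the top `ceiling(max_rank_fraction * M)` ranks, normalized
#' by the `k * window` rectangle, giving a value in `[0, 1]`. Because the
#' statistic is purely rank-based it is invariant to any strictly
#' monotone transform of a cell's counts, which buffers it against
#' depth and platform effects.
#'
#' Pathways are first restricted to genes present in `x`; sets with fewer
#' than `min_overlap` surviving genes are dropped with a message.
#'
#' @param x `ExpressionMatrix` (all common genes, not just HVGs)
#' @param pathways a `PathwayCollection`
#' @param max_rank_fraction fraction of the ranking used as the scoring
#'   window, in (0, 1]; default 0.05, the usual top-rank convention for
#'   this family of scorers
#' @param min_overlap minimum member genes a pathway must have in `x`
#' @param tie_break `"index"` (deterministic, default) or `"random"`
#' @param seed RNG seed used only when `tie_break = "random"`
#' @return a `PathwayScores` object: cells x pathways matrix of scores in
#'   `[0, 1]`
#' @export
score_pathways <- function(x, pathways, max_rank_fraction = 0.05,
                           min_overlap = 5L, tie_break = c("index", "random"),
                           seed = 1L) {
  tie_break <- match.arg(tie_break)
  stopifnot(max_rank_fraction > 0, max_rank_fraction <= 1)
  if (!nrow(x) || !ncol(x)) stop("empty expression matrix")
  genes <- colnames(x)
  member_idx <- lapply(pathways, function(g) which(genes %in% g))
  keep <- vapply(member_idx, length, 1L) >= min_overlap
  if (any(!keep)) {
    message("dropping ", sum(!keep), " pathway(s) with overlap < ",
            min_overlap, " in '", attr(pathways, "name"), "'")
  }
  member_idx <- member_idx[keep]
  if (!length(member_idx)) stop("no pathway survives the overlap filter")
  M <- ncol(x)
  N <- nrow(x)
  window <- as.integer(ceiling(max_rank_fraction * M))
  Q <- matrix(0, N, length(member_idx),
              dimnames = list(rownames(x), names(member_idx)))
  vals <- unclass(x)
  if (tie_break == "random") {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(as.integer(seed))
  }
  for (i in seq_len(N)) {
    tiebreaker <- if (tie_break == "index") seq_len(M) else sample.int(M)
    ord <- order(-vals[i, ], tiebreaker)
    rank_of_gene <- integer(M)
    rank_of_gene[ord] <- seq_len(M)
    for (j in seq_along(member_idx)) {
      hit_ranks <- rank_of_gene[member_idx[[j]]]
      hit_ranks <- hit_ranks[hit_ranks <= window]
      # area under the cumulative-hit step curve over ranks 1..window:
      # a hit at rank r contributes (window - r + 1) unit columns
      area <- sum(window - hit_ranks + 1L)
      Q[i, j] <- area / (length(member_idx[[j]]) * window)
    }
  }
  structure(Q, class = c("PathwayScores", "matrix", "array"))
}

#' Cell-cell similarity from pathway scores
#'
#' `S_ij = 1 / (1 + ||Q_i - Q_j||_2)`: Euclidean distance between the
#' cells' pathway-activity profiles, mapped to a similarity in (0, 1]
#' with unit diagonal.
#'
#' @param q `PathwayScores` (or any finite numeric matrix, cells in rows)
#' @return symmetric `SimilarityMatrix` with diagonal 1
#' @export
similarity_matrix <- function(q) {
  if (!all(is.finite(q))) stop("non-finite pathway scores")
  d <- as.matrix(stats::dist(unclass(q)))
  s <- 1 / (1 + d)
  # dist() leaves the matrix symmetric; enforce exactly for safety
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  dimnames(s) <- list(rownames(q), rownames(q))
  structure(s, class = c("SimilarityMatrix", "matrix", "array"))
}

#' Mutual nearest-neighbour cell graph
#'
#' An undirected edge (i, j) exists iff cell i is among the k most
#' similar cells to j (self excluded) AND j is among the k most similar
#' to i. Similarity ties at the k-th position are broken by cell index,
#' so the graph is deterministic. The adjacency is symmetric with zero
#' diagonal by construction.
#'
#' @param s `SimilarityMatrix`
#' @param k neighbourhood size, `0 < k < N`
#' @return a `CellGraph` (see [cell_graph()]), including the
#'   symmetrically normalized adjacency used by the graph convolutions
#' @export
mnn_graph <- function(s, k = 10L) {
  n <- nrow(s)
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < N (N = ", n, ")")
  nn <- matrix(FALSE, n, n)  # nn[i, j]: i is in the k-NN list of j
  for (j in seq_len(n)) {
    ord <- order(-s[, j], seq_len(n))
    ord <- ord[ord != j]
    nn[ord[seq_len(k)], j] <- TRUE
  }
  a <- (nn & t(nn)) * 1
  diag(a) <- 0
  dimnames(a) <- dimnames(s)
  cell_graph(a)
}

#' Construct a cell graph with symmetric adjacency normalization
#'
#' Stores the binary adjacency `A`, the self-loop degrees
#' `Dtilde = diag(A + I)` row sums, and the symmetrically normalized
#' propagation matrix `Atilde = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}`
#' used by the graph-convolutional auto-encoder. Self-loops guarantee
#' positive degrees, entries in `[0, 1]`, and a spectral radius of at
#' most 1.
#'
#' @param a symmetric binary adjacency matrix with zero diagonal
#' @return an object of class `CellGraph` with elements `adjacency`,
#'   `normalized`, `degrees`
#' @export
cell_graph <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(a != t(a))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal")
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary")
  deg <- rowSums(a) + 1
  inv_sqrt <- 1 / sqrt(deg)
  atil <- (a + diag(nrow(a))) * outer(inv_sqrt, inv_sqrt)
  structure(list(adjacency = a, normalized = atil, degrees = deg),
            class = "CellGraph")
}

#' Recompute the normalized adjacency of a graph
#' @param g a `CellGraph` (or bare adjacency matrix)
#' @return a `CellGraph` with the normalization attached
#' @export
normalize_adjacency <- function(g) {
  a <- if (inherits(g, "CellGraph")) g$adjacency else g
  cell_graph(a)
}

#' @export
print.CellGraph <- function(x, ...) {
  cat(sprintf("CellGraph: %d cells, %d undirected edges\n",
              nrow(x$adjacency), sum(x$adjacency) / 2))
  invisible(x)
}

#' Export a cell graph
#'
#' @param g a `CellGraph`
#' @param path output file
#' @param format `"edgelist"` (TSV of `from TAB to`, i < j) or `"mtx"`
#'   (Matrix Market sparse adjacency)
#' @return `path`, invisibly
#' @export
write_graph <- function(g, path, format = c("edgelist", "mtx")) {
  format <- match.arg(format)
  a <- g$adjacency
  if (format == "edgelist") {
    idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    ids <- rownames(a)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(a)))
    utils::write.table(
      data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(a, sparse = TRUE), path)
  }
  invisible(path)
}

#' Write pathway scores as TSV (cells x pathways)
#' @param q `PathwayScores`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_scores <- function(q, path) {
  df <- data.frame(cell_id = rownames(q), unclass(q),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
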