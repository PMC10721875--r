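#' Restrict two expression matrices to their common genes
#'
#' Reference and query data rarely share an identical gene universe; all
#' downstream steps operate on the intersection. Shared genes keep the
#' reference matrix's column order in both outputs.
#'
#' @param train,test `ExpressionMatrix` objects
#' @return list with elements `train` and `test`, both restricted to the
#'   shared genes in identical order
#' @export
intersect_genes <- function(train, test) {
  shared <- intersect(colnames(train), colnames(test))
  if (!length(shared)) stop("gene intersection is empty")
  list(
    train = subset_expression(train, genes = shared),
    test = subset_expression(test, genes = shared)
  )
}

#' Rank genes by one-way ANOVA F across cell-type labels
#'
#' Highly variable gene (HVG) selection: genes are scored by the one-way
#' ANOVA F statistic of expression across the label groups and the top
#' `n_genes` are returned. A gene with zero within-group and zero
#' between-group variance gets F = 0 (ranked last); zero within-group but
#' positive between-group variance gives F = Inf (ranked above every
#' finite F). Ties are broken by input gene order, so the ranking is
#' deterministic and invariant to cell order.
#'
#' @param train labeled `ExpressionMatrix` with at least two classes and
#'   at least two cells per class
#' @param n_genes number of genes to keep (capped at the gene count)
#' @return character vector of selected gene ids, in decreasing F order
#' @export
select_hvgs_anova <- function(train, n_genes = 2000L) {
  labels <- cell_labels(train)
  if (is.null(labels)) stop("training data has no labels")
  grp <- factor(labels)
  if (nlevels(grp) < 2L) stop("need at least 2 label classes")
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    stop("classes with fewer than 2 cells: ", paste(small, collapse = ", "))
  }
  f <- anova_f_stats(unclass(train), grp)
  ord <- order(-f, seq_along(f))
  colnames(train)[ord[seq_len(min(n_genes, ncol(train)))]]
}

# Vectorised per-gene one-way F statistic across groups.
anova_f_stats <- function(X, grp) {
  n <- nrow(X)
  g <- nlevels(grp)
  counts <- tabulate(grp, g)
  group_means <- rowsum(X, grp, reorder = TRUE) / counts   # g x M
  grand_mean <- colSums(X) / n
  ssb <- colSums(counts * (t(t(group_means) - grand_mean))^2)
  ssw <- colSums((X - group_means[as.integer(grp), , drop = FALSE])^2)
  # a gene that is (numerically) constant has F defined as 0
  const <- (ssb + ssw) <= 1e-12 * n * (grand_mean^2 + 1)
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  f[const] <- 0
  f
}

#' Median (cell-size) normalization
#'
#' Rescales every cell so that its total count equals the average total
#' across cells: `x_ij / sum_j(x_ij) * (grand_total / N)`. Removes
#' cell-size (library depth) differences while preserving the dataset's
#' overall scale.
#'
#' @param x `ExpressionMatrix`; every cell must have a positive total
#' @return normalized `ExpressionMatrix` (labels preserved); all row sums
#'   equal `grand_total / N`
#' @export
median_normalize <- function(x) {
  rs <- rowSums(x)
  bad <- rownames(x)[rs == 0]
  if (length(bad)) {
    stop("cells with zero total count: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  target <- sum(rs) / nrow(x)
  expression_matrix(unclass(x) * (target / rs), labels = cell_labels(x))
}

#' Read a two-column homolog mapping table
#'
#' Loads `source_gene TAB target_gene` rows (e.g. mouse -> human symbols
#' from HomoloGene) and filters them to a strict one-to-one mapping: any
#' source or target symbol that appears more than once is dropped.
#'
#' @param path TSV file; an optional header line is detected and skipped
#' @return data.frame with columns `source` and `target`, one-to-one
#' @export
read_homolog_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("homolog table must have two tab-separated columns")
  if (identical(tolower(df[1L, 1L]), "source_gene")) df <- df[-1L, , drop = FALSE]
  homolog_table(df[[1L]], df[[2L]])
}

#' Construct a one-to-one homolog table
#' @param source,target character vectors of gene symbols
#' @return data.frame with unique `source` and unique `target` columns
#' @export
homolog_table <- function(source, target) {
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   stringsAsFactors = FALSE)
  df <- df[!(df$source %in% df$source[duplicated(df$source)]) &
             !(df$target %in% df$target[duplicated(df$target)]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rename genes through a homolog table
#'
#' Genes absent from the table are dropped; the rest are renamed
#' source -> target, preserving column order. Used to bring e.g. mouse
#' data onto human gene symbols before pathway scoring.
#'
#' @param x `ExpressionMatrix`
#' @param table one-to-one homolog table (see [homolog_table()])
#' @return `ExpressionMatrix` over the renamed surviving genes
#' @export
map_homologs <- function(x, table) {
  idx <- match(colnames(x), table$source)
  keep <- which(!is.na(idx))
  if (!length(keep)) stop("no genes survive homolog mapping")
  new_names <- table$target[idx[keep]]
  if (anyDuplicated(new_names)) {
    stop("homolog renaming would create duplicate gene ids: ",
         paste(unique(new_names[duplicated(new_names)]), collapse = ", "))
  }
  m <- unclass(x)[, keep, drop = FALSE]
  colnames(m) <- new_names
  expression_matrix(m, labels = cell_labels(x))
}
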