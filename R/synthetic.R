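# Seeded generator of labeled expression datasets with pathway-driven
# class structure, dropout zeros and batch effects. Every stage of the
# pipeline, and the end-to-end benchmarks, run on its output.

default_class_activation <- function(n_classes, ppc) {
  # round-robin: pathway j belongs to class ((j-1) mod K) + 1
  lapply(seq_len(n_classes), function(c) {
    which(((seq_len(ppc) - 1L) %% n_classes) + 1L == c)
  })
}

build_truth <- function(n_genes, n_classes, n_pathway_collections,
                        pathways_per_collection, genes_per_pathway,
                        class_activation) {
  if (pathways_per_collection * genes_per_pathway > n_genes) {
    stop("pathways_per_collection * genes_per_pathway (",
         pathways_per_collection * genes_per_pathway,
         ") exceeds n_genes (", n_genes, ")")
  }
  gene_ids <- paste0("g", seq_len(n_genes))
  collections <- vector("list", n_pathway_collections)
  members <- vector("list", n_pathway_collections)
  for (v in seq_len(n_pathway_collections)) {
    chosen <- sample.int(n_genes, pathways_per_collection * genes_per_pathway)
    idx <- split(chosen, rep(seq_len(pathways_per_collection),
                             each = genes_per_pathway))
    names(idx) <- paste0("C", v, "_P", seq_len(pathways_per_collection))
    members[[v]] <- idx
    collections[[v]] <- pathway_collection(
      lapply(idx, function(i) gene_ids[i]), name = paste0("collection", v))
  }
  if (is.null(class_activation)) {
    class_activation <- replicate(
      n_pathway_collections,
      default_class_activation(n_classes, pathways_per_collection),
      simplify = FALSE)
  }
  # K x M: is gene g up-regulated in class c (via any collection)?
  active <- matrix(FALSE, n_classes, n_genes)
  for (v in seq_len(n_pathway_collections)) {
    for (c in seq_len(n_classes)) {
      for (p in class_activation[[v]][[c]]) {
        active[c, members[[v]][[p]]] <- TRUE
      }
    }
  }
  list(gene_ids = gene_ids, collections = collections, members = members,
       class_activation = class_activation, active = active)
}

sample_counts <- function(classes, truth, base_log_mean, activation_effect,
                          log_sd, dropout_rate, dropout_model, model, nb_size,
                          gene_log_shift, cell_prefix) {
  n <- length(classes)
  M <- length(truth$gene_ids)
  mu <- base_log_mean + activation_effect * truth$active   # K x M log means
  logx <- mu[classes, , drop = FALSE] +
    matrix(stats::rnorm(n * M, sd = log_sd), n, M)
  logx <- sweep(logx, 2L, gene_log_shift, "+")
  counts <- if (model == "lognormal") {
    round(exp(logx))
  } else {
    matrix(stats::rnbinom(n * M, mu = exp(logx), size = nb_size), n, M)
  }
  if (dropout_rate > 0) {
    p <- if (dropout_model == "independent") {
      matrix(dropout_rate, n, M)
    } else {
      # expression-dependent: low-expression entries drop out more often,
      # rescaled so the average rate stays at dropout_rate
      w <- exp(-logx)
      pmin(dropout_rate * w / mean(w), 0.95)
    }
    counts[matrix(stats::runif(n * M), n, M) < p] <- 0
  }
  dimnames(counts) <- list(paste0(cell_prefix, seq_len(n)), truth$gene_ids)
  counts
}

#' Simulate a labeled single-cell expression dataset
#'
#' Genes are organized into pathway collections (gene sets sampled from
#' the gene universe; sets within a collection are disjoint, collections
#' may overlap, as real KEGG/Reactome do). Each class up-regulates a
#' disjoint subset of each collection's pathways by `activation_effect`
#' on the log scale; counts are exponentiated Gaussian log-expression
#' rounded to integers (a negative-binomial option is available), with
#' independent dropout zeroing at `dropout_rate`. All draws are seeded.
#'
#' @param n_cells_per_class cells per class (default 100); a vector of
#'   length `n_classes` gives unbalanced class sizes
#' @param n_classes number of cell types (default 3)
#' @param n_genes gene universe size (default 600)
#' @param n_pathway_collections number of views (default 2)
#' @param pathways_per_collection gene sets per collection (default 6)
#' @param genes_per_pathway genes per set (default 30)
#' @param activation_effect log-scale mean shift of class-active pathway
#'   genes (default 1.5; 0 removes all class signal)
#' @param dropout_rate probability an entry is zeroed, in `[0, 1)`
#' @param base_log_mean baseline log-expression (default 1)
#' @param log_sd log-expression standard deviation (default 0.5)
#' @param model `"lognormal"` (default) or `"nb"`
#' @param nb_size negative-binomial size when `model = "nb"`
#' @param dropout_model `"independent"` (default) or `"expression"`
#' @param class_activation optional override: list (one per collection)
#'   of lists (one per class) of active pathway indices; used e.g. to
#'   make two collections disambiguate different class pairs
#' @param gene_log_shift optional per-gene additive log shift (batch
#'   effect), length `n_genes`
#' @param cell_prefix prefix for cell ids
#' @param seed RNG seed
#' @return list with `expression` (labeled [expression_matrix()]),
#'   `pathways` (list of `PathwayCollection`), and `truth` (class-pathway
#'   assignments, per-class active-gene matrix, generator settings)
#' @export
simulate_cells <- function(n_cells_per_class = 100L, n_classes = 3L,
                           n_genes = 600L, n_pathway_collections = 2L,
                           pathways_per_collection = 6L,
                           genes_per_pathway = 30L, activation_effect = 1.5,
                           dropout_rate = 0.3, base_log_mean = 1,
                           log_sd = 0.5, model = c("lognormal", "nb"),
                           nb_size = 2, dropout_model = c("independent",
                                                          "expression"),
                           class_activation = NULL, gene_log_shift = NULL,
                           cell_prefix = "cell", seed = 1L) {
  model <- match.arg(model)
  dropout_model <- match.arg(dropout_model)
  stopifnot(n_cells_per_class > 0, n_classes > 0, n_genes > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (is.null(gene_log_shift)) gene_log_shift <- numeric(n_genes)
  res <- with_seed(seed, {
    truth <- build_truth(n_genes, n_classes, n_pathway_collections,
                         pathways_per_collection, genes_per_pathway,
                         class_activation)
    classes <- rep(seq_len(n_classes),
                   times = rep_len(n_cells_per_class, n_classes))
    counts <- sample_counts(classes, truth, base_log_mean, activation_effect,
                            log_sd, dropout_rate, dropout_model, model,
                            nb_size, gene_log_shift, cell_prefix)
    list(truth = truth, classes = classes, counts = counts)
  })
  labels <- paste0("class_", res$classes)
  expr <- expression_matrix(res$counts, labels = labels)
  truth <- res$truth
  truth$settings <- list(
    n_cells_per_class = n_cells_per_class, n_classes = n_classes,
    n_genes = n_genes, activation_effect = activation_effect,
    dropout_rate = dropout_rate, base_log_mean = base_log_mean,
    log_sd = log_sd, model = model, seed = seed)
  list(expression = expr, pathways = truth$collections, truth = truth)
}

#' Simulate a reference/query dataset pair with a batch effect
#'
#' Draws two datasets from the same class-pathway ground truth: the
#' query receives an independent dropout draw and per-gene multiplicative
#' batch factors (log-normal with spread `batch_shift`), emulating a
#' cross-platform setting. Optionally one class is withheld from the
#' reference to emulate the unknown-cell-type setting; those query cells
#' are marked `"unknown"` in `truth$query_expected`.
#'
#' @inheritParams simulate_cells
#' @param batch_shift standard deviation of the per-gene log batch
#'   factors applied to the query (0 = identically distributed pair)
#' @param withhold_class optional class label (e.g. `"class_3"`) absent
#'   from the reference but present in the query
#' @param n_query_per_class query cells per class (defaults to
#'   `n_cells_per_class`)
#' @param train_draw_seed optional separate seed for the reference draw,
#'   so several reference datasets can be generated from the same
#'   class-pathway ground truth (used by sequential pre-training
#'   benchmarks)
#' @return list with `train`, `test` (labeled `ExpressionMatrix`),
#'   `pathways`, `truth` (including `query_expected`, the test labels
#'   with the withheld class replaced by `"unknown"`)
#' @export
simulate_query_pair <- function(n_cells_per_class = 100L, n_classes = 3L,
                                n_genes = 600L, n_pathway_collections = 2L,
                                pathways_per_collection = 6L,
                                genes_per_pathway = 30L,
                                activation_effect = 1.5, dropout_rate = 0.3,
                                base_log_mean = 1, log_sd = 0.5,
                                model = c("lognormal", "nb"), nb_size = 2,
                                dropout_model = c("independent", "expression"),
                                class_activation = NULL, batch_shift = 0.2,
                                withhold_class = NULL,
                                n_query_per_class = NULL,
                                train_draw_seed = NULL, seed = 1L) {
  model <- match.arg(model)
  dropout_model <- match.arg(dropout_model)
  if (is.null(n_query_per_class)) n_query_per_class <- n_cells_per_class
  seeds <- fan_out_seeds(seed, 4L)
  if (!is.null(train_draw_seed)) {
    seeds[2L] <- fan_out_seeds(train_draw_seed, 1L)
  }
  truth <- with_seed(seeds[1L], {
    build_truth(n_genes, n_classes, n_pathway_collections,
                pathways_per_collection, genes_per_pathway, class_activation)
  })
  class_names <- paste0("class_", seq_len(n_classes))
  train_classes <- seq_len(n_classes)
  if (!is.null(withhold_class)) {
    wi <- match(withhold_class, class_names)
    if (is.na(wi)) stop("withhold_class not among ", toString(class_names))
    train_classes <- setdiff(train_classes, wi)
  }
  tr_sizes <- rep_len(n_cells_per_class, n_classes)
  tr_idx <- rep(train_classes, times = tr_sizes[train_classes])
  te_idx <- rep(seq_len(n_classes), times = rep_len(n_query_per_class,
                                                    n_classes))
  train_counts <- with_seed(seeds[2L], {
    sample_counts(tr_idx, truth, base_log_mean, activation_effect, log_sd,
                  dropout_rate, dropout_model, model, nb_size,
                  numeric(n_genes), "ref_")
  })
  test_counts <- with_seed(seeds[3L], {
    shift <- stats::rnorm(n_genes, sd = batch_shift)
    sample_counts(te_idx, truth, base_log_mean, activation_effect, log_sd,
                  dropout_rate, dropout_model, model, nb_size, shift, "query_")
  })
  train <- expression_matrix(train_counts, labels = class_names[tr_idx])
  test <- expression_matrix(test_counts, labels = class_names[te_idx])
  query_expected <- class_names[te_idx]
  if (!is.null(withhold_class)) {
    query_expected[query_expected == withhold_class] <- "unknown"
  }
  truth$query_expected <- query_expected
  truth$settings <- list(
    n_cells_per_class = n_cells_per_class, n_classes = n_classes,
    n_genes = n_genes, activation_effect = activation_effect,
    dropout_rate = dropout_rate, batch_shift = batch_shift,
    withhold_class = withhold_class, model = model, seed = seed)
  list(train = train, test = test, pathways = truth$collections,
       truth = truth)
}

#' Write a simulated dataset in standard on-disk formats
#'
#' Exports the expression matrix (CSV and MTX triplet), labels (TSV) and
#' every pathway collection (GMT) so the package's own readers can be
#' exercised against generated data.
#'
#' @param dataset result of [simulate_cells()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_synthetic <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.csv"), "csv")
  write_expression(dataset$expression, file.path(dir, "mtx"), "mtx_dir")
  labs <- cell_labels(dataset$expression)
  utils::write.table(
    data.frame(cell_id = rownames(dataset$expression), label = labs),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (p in dataset$pathways) {
    write_gmt(p, file.path(dir, paste0(attr(p, "name"), ".gmt")))
  }
  invisible(dir)
}
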