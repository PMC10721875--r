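#' Tuning parameters for the annotation pipeline
#'
#' Collects every tunable of the pipeline with its default. Defaults are
#' desk-scale settings documented in the methods vignette; all are
#' overridable per fit.
#'
#' @param n_hvgs number of ANOVA-selected highly variable genes (2000)
#' @param max_rank_fraction pathway-scoring window as a fraction of the
#'   gene ranking (0.05)
#' @param min_overlap minimum genes a pathway must share with the data (5)
#' @param k_mnn mutual-nearest-neighbour graph size (10)
#' @param mask_fraction fraction of non-zero entries masked during
#'   auto-encoder training (0.1)
#' @param latent_dim per-view embedding width `d` (64)
#' @param ae_epochs,ae_lr auto-encoder epochs (200) and Adam rate (1e-3)
#' @param subspace_dim shared latent width `d_s` (32)
#' @param lambda weight of the margin label loss (1)
#' @param mv_lr,mv_epochs,mv_epochs_test,mv_tol subspace learning rate
#'   (1), train epochs (300), query-inference epochs (100), and
#'   convergence tolerance on the label loss (1e-4)
#' @param hidden_dim classifier hidden width (64)
#' @param clf_epochs,clf_lr classifier epochs (200) and Adam rate (1e-3)
#' @param unknown_threshold rejection threshold on the top-class
#'   probability (0.5)
#' @param log_transform apply `log1p` after median normalization
#'   (off by default)
#' @param verbose emit per-stage progress messages
#' @return list of class `scpml_control`
#' @export
scpml_control <- function(n_hvgs = 2000L, max_rank_fraction = 0.05,
                          min_overlap = 5L, k_mnn = 10L, mask_fraction = 0.1,
                          latent_dim = 64L, ae_epochs = 200L, ae_lr = 1e-3,
                          subspace_dim = 32L, lambda = 1, mv_lr = 1,
                          mv_epochs = 300L, mv_epochs_test = 100L,
                          mv_tol = 1e-4, hidden_dim = 64L, clf_epochs = 200L,
                          clf_lr = 1e-3, unknown_threshold = 0.5,
                          log_transform = FALSE, verbose = FALSE) {
  structure(as.list(environment()), class = "scpml_control")
}

stage_msg <- function(control, ...) {
  if (isTRUE(control$verbose)) message("[scpml] ", ...)
}

# Pre-processing shared by training and annotation: restrict to the gene
# panel (absent genes become zero columns), median-normalize, optional log.
prepare_features <- function(x, hvgs, control) {
  m <- matrix(0, nrow(x), length(hvgs),
              dimnames = list(rownames(x), hvgs))
  present <- intersect(hvgs, colnames(x))
  m[, present] <- unclass(x)[, present]
  xhat <- median_normalize(expression_matrix(m, labels = cell_labels(x)))
  if (isTRUE(control$log_transform)) {
    xhat <- expression_matrix(log1p(unclass(xhat)),
                              labels = cell_labels(xhat))
  }
  xhat
}

# Pathway scores + MNN graph for one view.
build_view_graph <- function(x, pathways, control) {
  q <- score_pathways(x, pathways,
                      max_rank_fraction = control$max_rank_fraction,
                      min_overlap = control$min_overlap)
  s <- similarity_matrix(q)
  k <- min(control$k_mnn, nrow(s) - 1L)
  mnn_graph(s, k)
}

fit_components <- function(train, pathways, control, seed, hvgs = NULL,
                           warm = NULL, label_alphabet = NULL,
                           view_scales = NULL) {
  labels <- cell_labels(train)
  if (is.null(labels)) stop("stage preprocess: training data has no labels")
  if (!is.null(label_alphabet) &&
      !all(labels %in% label_alphabet)) {
    stop("stage preprocess: labels outside the model's alphabet: ",
         paste(setdiff(unique(labels), label_alphabet), collapse = ", "))
  }
  n_views <- length(pathways)
  if (!n_views) stop("stage preprocess: need at least one pathway collection")
  seeds <- fan_out_seeds(seed, n_views + 2L)

  stage_msg(control, "selecting HVGs")
  if (is.null(hvgs)) {
    hvgs <- select_hvgs_anova(train, control$n_hvgs)
  }
  xhat <- prepare_features(train, hvgs, control)

  stage_msg(control, "building ", n_views, " view graph(s)")
  views <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    g <- tryCatch(build_view_graph(train, pathways[[v]], control),
                  error = function(e) stop("stage pathway_graph (view ", v,
                                           "): ", conditionMessage(e)))
    nm <- attr(pathways[[v]], "name")
    if (is.null(nm)) nm <- paste0("view", v)
    stage_msg(control, "training auto-encoder for view '", nm, "'")
    views[[v]] <- tryCatch(
      train_autoencoder(xhat, g, latent_dim = control$latent_dim,
                        mask_fraction = control$mask_fraction,
                        epochs = control$ae_epochs, lr = control$ae_lr,
                        seed = seeds[v], view_name = nm,
                        init = if (is.null(warm)) NULL else
                          warm$views[[v]]),
      error = function(e) stop("stage graph_autoencoder (view ", v, "): ",
                               conditionMessage(e)))
  }

  # bring the views onto a comparable scale before fusion: each embedding
  # is divided by its mean row norm (train-derived; reused at query time)
  if (is.null(view_scales)) {
    view_scales <- vapply(views, function(v) {
      s <- mean(sqrt(rowSums(v$H^2)))
      if (s > 0) s else 1
    }, 1)
  }
  fusion_views <- mapply(function(v, s) {
    v$H <- v$H / s
    v
  }, views, view_scales, SIMPLIFY = FALSE)

  stage_msg(control, "fitting multi-view subspace")
  mv <- tryCatch(
    fit_multiview(fusion_views, labels, subspace_dim = control$subspace_dim,
                  lambda = control$lambda, lr = control$mv_lr,
                  epochs = control$mv_epochs, tol = control$mv_tol,
                  seed = seeds[n_views + 1L],
                  init_thetas = if (is.null(warm)) NULL else warm$mv$thetas,
                  label_alphabet = label_alphabet),
    error = function(e) stop("stage multiview: ", conditionMessage(e)))

  stage_msg(control, "training classifier")
  clf <- tryCatch(
    train_classifier(mv$h, labels, hidden = control$hidden_dim,
                     epochs = control$clf_epochs, lr = control$clf_lr,
                     seed = seeds[n_views + 2L],
                     init = if (is.null(warm)) NULL else warm$classifier,
                     label_alphabet = label_alphabet),
    error = function(e) stop("stage classify: ", conditionMessage(e)))

  train_pred <- predict_cells(mv$h, clf, threshold = 1e-12)
  list(hvgs = hvgs, views = views, view_scales = view_scales, mv = mv,
       classifier = clf,
       training_accuracy = mean(train_pred$label == labels))
}

#' Fit a pathway-based multi-view annotation model
#'
#' Runs the full training path on a labeled reference: ANOVA HVG
#' selection and median normalization; per pathway collection, rank-AUC
#' pathway scoring over all genes, a mutual-nearest-neighbour cell
#' graph, and a masked graph-convolutional auto-encoder; fusion of the
#' per-view embeddings into a shared latent subspace with a margin-based
#' label loss; and a softmax classifier over the latent space. All
#' randomness fans out from `seed`, so the same call is bitwise
#' reproducible.
#'
#' @param train labeled [expression_matrix()] (cells x genes, counts)
#' @param pathways a `PathwayCollection` or list of them; each defines
#'   one view
#' @param control pipeline settings from [scpml_control()]
#' @param seed root seed
#' @return an object of class `scpml` with components `hvgs`, `views`
#'   (per-view `ViewEmbedding`), `view_scales` (train-derived per-view
#'   normalization reused at query time), `mv` (`MultiviewState`),
#'   `classifier`, `pathways`, `control`, `seed`, `training_accuracy`
#' @seealso [predict.scpml()], [scpml_sequential()], [scpml_save()]
#' @export
#' @examples
#' sim <- simulate_cells(n_cells_per_class = 30, n_genes = 200,
#'                       genes_per_pathway = 15, seed = 7)
#' ctrl <- scpml_control(ae_epochs = 30, mv_epochs = 50, clf_epochs = 50,
#'                       n_hvgs = 150)
#' fit <- scpml(sim$expression, sim$pathways, control = ctrl, seed = 7)
#' fit
scpml <- function(train, pathways, control = scpml_control(), seed = 1L) {
  if (inherits(pathways, "PathwayCollection")) pathways <- list(pathways)
  comp <- fit_components(train, pathways, control, seed)
  structure(c(comp, list(pathways = pathways, control = control,
                         seed = as.integer(seed),
                         label_alphabet = comp$classifier$label_alphabet)),
            class = "scpml")
}

#' @export
print.scpml <- function(x, ...) {
  cat("Pathway-based multi-view annotation model\n")
  cat(sprintf("  views: %d (%s)\n", length(x$views),
              paste(vapply(x$views, `[[`, "", "view_name"), collapse = ", ")))
  cat(sprintf("  cells: %d  gene panel: %d  classes: %d\n",
              nrow(x$mv$h), length(x$hvgs), length(x$label_alphabet)))
  cat(sprintf("  training accuracy: %.3f\n", x$training_accuracy))
  invisible(x)
}

#' @export
summary.scpml <- function(object, ...) {
  cat("Pathway-based multi-view annotation model\n\n")
  cat("Classes:", paste(object$label_alphabet, collapse = ", "), "\n")
  cat(sprintf("Gene panel: %d HVGs; views: %d; latent widths d = %d, d_s = %d\n",
              length(object$hvgs), length(object$views),
              object$control$latent_dim, object$control$subspace_dim))
  for (v in object$views) {
    cat(sprintf("  view '%s': final masked loss %.4g\n", v$view_name,
                utils::tail(v$loss_history, 1)))
  }
  lh <- object$mv$loss_history
  cat(sprintf("Subspace: %d epochs, objective %.4g -> %.4g\n",
              object$mv$epochs_run, lh$objective[1L],
              utils::tail(lh$objective, 1)))
  cat(sprintf("Classifier: cross-entropy %.4g -> %.4g; training accuracy %.3f\n",
              object$classifier$loss_history[1L],
              utils::tail(object$classifier$loss_history, 1),
              object$training_accuracy))
  invisible(object)
}

#' Annotate query cells with a fitted model
#'
#' The query is pre-processed and graphed independently of training
#' (the model never sees query data during fitting): pathway scores and
#' MNN graphs are built from the query cells alone, the frozen per-view
#' encoders embed them, latent vectors are inferred by reconstruction
#' against the frozen view mappings, and the classifier assigns labels
#' with open-set rejection.
#'
#' @param object fitted `scpml` model
#' @param newdata `ExpressionMatrix` of query cells; must cover at least
#'   half of the model's gene panel (missing panel genes are treated as
#'   unobserved zeros)
#' @param threshold rejection threshold (defaults to the fitted
#'   control's `unknown_threshold`)
#' @param ... unused
#' @return an `scpml_prediction` data.frame (`cell_id`, `label`,
#'   `confidence`) with the probability matrix attached
#' @export
predict.scpml <- function(object, newdata,
                          threshold = object$control$unknown_threshold, ...) {
  if (missing(newdata) || is.null(newdata)) stop("newdata is required")
  if (!nrow(newdata) || !ncol(newdata)) stop("empty query matrix")
  control <- object$control
  coverage <- mean(object$hvgs %in% colnames(newdata))
  if (coverage < 0.5) {
    stop(sprintf(paste0("query covers only %.1f%% of the model's %d-gene ",
                        "panel (need >= 50%%)"),
                 100 * coverage, length(object$hvgs)))
  }
  xhat <- prepare_features(newdata, object$hvgs, control)
  views_test <- vector("list", length(object$views))
  for (v in seq_along(object$views)) {
    g <- tryCatch(build_view_graph(newdata, object$pathways[[v]], control),
                  error = function(e) stop("stage pathway_graph (view ", v,
                                           "): ", conditionMessage(e)))
    h <- embed_test(xhat, g, object$views[[v]]$W1) / object$view_scales[v]
    views_test[[v]] <- structure(
      list(H = h, W1 = object$views[[v]]$W1, W2 = object$views[[v]]$W2,
           view_name = object$views[[v]]$view_name,
           latent_dim = object$views[[v]]$latent_dim,
           loss_history = numeric(0)),
      class = "ViewEmbedding")
  }
  h_test <- infer_latent_test(views_test, object$mv,
                              epochs = control$mv_epochs_test)
  predict_cells(h_test, object$classifier, threshold = threshold)
}

#' Annotate query cells (function form of [predict.scpml()])
#' @param model fitted `scpml` model
#' @param test query `ExpressionMatrix`
#' @param ... passed to [predict.scpml()]
#' @return an `scpml_prediction`
#' @export
annotate_cells <- function(model, test, ...) {
  predict(model, newdata = test, ...)
}

#' Sequential pre-training over multiple reference datasets
#'
#' Trains on the first dataset, then continues optimization on each
#' subsequent dataset from the saved parameters (earlier data is never
#' revisited). The HVG panel and the class alphabet are frozen by the
#' first dataset; a later dataset introducing a label outside that
#' alphabet is an error.
#'
#' @param datasets ordered list of labeled `ExpressionMatrix` objects
#' @param pathways pathway collection(s), as in [scpml()]
#' @param control [scpml_control()]
#' @param seed root seed; stage seeds are derived per dataset
#' @return an `scpml` model carrying the accumulated parameters
#' @export
scpml_sequential <- function(datasets, pathways,
                             control = scpml_control(), seed = 1L) {
  if (!length(datasets)) stop("need at least one dataset")
  if (inherits(pathways, "PathwayCollection")) pathways <- list(pathways)
  model <- scpml(datasets[[1L]], pathways, control = control, seed = seed)
  if (length(datasets) == 1L) return(model)
  stage_seeds <- fan_out_seeds(seed + 1L, length(datasets) - 1L)
  for (i in seq_along(datasets)[-1L]) {
    comp <- fit_components(datasets[[i]], pathways, control,
                           seed = stage_seeds[i - 1L], hvgs = model$hvgs,
                           warm = model,
                           label_alphabet = model$label_alphabet,
                           view_scales = model$view_scales)
    model$views <- comp$views
    model$mv <- comp$mv
    model$classifier <- comp$classifier
    model$training_accuracy <- comp$training_accuracy
  }
  model
}

#' Save / load a fitted model
#'
#' Serializes the full model state (gene panel, per-view encoder
#' weights, subspace mappings, classifier, settings) so that a reloaded
#' model annotates identically to the in-memory one.
#'
#' @param model fitted `scpml` model
#' @param path file path (conventionally `.rds`)
#' @return `scpml_save`: `path` invisibly; `scpml_load`: the model
#' @export
scpml_save <- function(model, path) {
  stopifnot(inherits(model, "scpml"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname scpml_save
#' @export
scpml_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "scpml")) stop("not a saved scpml model: ", path)
  model
}
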