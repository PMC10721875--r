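# Two-layer softmax classifier over the shared latent representation,
# with open-set rejection of low-confidence query cells.

#' Forward pass of the latent-space classifier
#'
#' `softmax(W2 ReLU(W1 h + b1) + b2)`, computed row-wise with
#' max-subtraction so extreme logits stay finite.
#'
#' @param h cells x d_s latent matrix (rows are classified independently)
#' @param params `ClassifierParams` from [train_classifier()]
#' @return cells x C probability matrix; every row sums to 1
#' @export
classifier_forward <- function(h, params) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(params$W1)) {
    stop("latent width ", ncol(h), " but classifier expects ", nrow(params$W1))
  }
  a1 <- relu(h %*% params$W1 + rep(params$b1, each = nrow(h)))
  logits <- a1 %*% params$W2 + rep(params$b2, each = nrow(h))
  p <- softmax_rows(logits)
  colnames(p) <- params$label_alphabet
  rownames(p) <- rownames(h)
  p
}

#' Train the latent-space classifier
#'
#' Minimizes the cross-entropy of one-hot targets under the two-layer
#' softmax network with full-batch Adam; the latent matrix is frozen
#' (the classifier is fit after subspace learning, not jointly).
#' Log-probabilities are clipped at 1e-12.
#'
#' @param h cells x d_s latent training matrix
#' @param labels per-cell class labels (at least two classes)
#' @param hidden hidden-layer width (default 64)
#' @param epochs training epochs (default 200)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed seed for weight initialization
#' @param init optional warm start: existing `ClassifierParams` to
#'   continue training from (alphabet must match)
#' @param label_alphabet optional fixed class alphabet
#' @return `ClassifierParams`: list with `W1`, `b1`, `W2`, `b2`,
#'   `label_alphabet`, `loss_history`
#' @export
train_classifier <- function(h, labels, hidden = 64L, epochs = 200L,
                             lr = 1e-3, seed = 1L, init = NULL,
                             label_alphabet = NULL) {
  h <- as.matrix(h)
  labels <- as.character(labels)
  if (length(labels) != nrow(h)) stop("labels length != cell count")
  alphabet <- if (is.null(label_alphabet)) sort(unique(labels))
              else label_alphabet
  if (!all(labels %in% alphabet)) {
    stop("labels outside the alphabet: ",
         paste(setdiff(unique(labels), alphabet), collapse = ", "))
  }
  if (length(alphabet) < 2L) stop("need at least 2 classes to train")
  n <- nrow(h)
  C <- length(alphabet)
  y <- matrix(0, n, C)
  y[cbind(seq_len(n), match(labels, alphabet))] <- 1

  params <- if (is.null(init)) {
    with_seed(seed, list(
      W1 = init_weights(ncol(h), hidden), b1 = numeric(hidden),
      W2 = init_weights(hidden, C), b2 = numeric(C)
    ))
  } else {
    if (!identical(init$label_alphabet, alphabet)) {
      stop("warm-start alphabet differs from requested alphabet")
    }
    list(W1 = init$W1, b1 = init$b1, W2 = init$W2, b2 = init$b2)
  }
  opt <- adam_init(params, lr = lr)
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    z1 <- h %*% params$W1 + rep(params$b1, each = n)
    a1 <- relu(z1)
    logits <- a1 %*% params$W2 + rep(params$b2, each = n)
    p <- softmax_rows(logits)
    loss <- -sum(y * log(pmax(p, 1e-12))) / n
    if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
    loss_history[ep] <- loss
    dz2 <- (p - y) / n
    dW2 <- crossprod(a1, dz2)
    db2 <- colSums(dz2)
    dz1 <- (dz2 %*% t(params$W2)) * (z1 > 0)
    dW1 <- crossprod(h, dz1)
    db1 <- colSums(dz1)
    upd <- adam_step(opt, params,
                     list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
    opt <- upd$state
    params <- upd$params
  }
  structure(c(params, list(label_alphabet = alphabet,
                           loss_history = loss_history)),
            class = "ClassifierParams")
}

#' Classify query cells with open-set rejection
#'
#' Each cell is assigned the highest-probability class unless no class
#' reaches the confidence threshold, in which case it is labeled with
#' the reserved token `"unknown"` — the standard rule for flagging cell
#' types absent from the reference. Probability ties are broken by
#' alphabet order.
#'
#' @param h cells x d_s latent query matrix
#' @param params trained `ClassifierParams`
#' @param threshold rejection threshold in (0, 1]; default 0.5
#' @return data.frame of class `scpml_prediction` with columns
#'   `cell_id`, `label`, `confidence`; the full probability matrix is
#'   attached as attribute `"probabilities"`
#' @export
predict_cells <- function(h, params, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  p <- classifier_forward(h, params)
  best <- max.col(p, ties.method = "first")
  conf <- p[cbind(seq_len(nrow(p)), best)]
  label <- ifelse(conf < threshold, "unknown", params$label_alphabet[best])
  out <- data.frame(
    cell_id = if (is.null(rownames(p))) as.character(seq_len(nrow(p)))
              else rownames(p),
    label = label, confidence = conf,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "probabilities") <- p
  class(out) <- c("scpml_prediction", "data.frame")
  out
}

#' Write predictions as TSV
#' @param pred an `scpml_prediction`
#' @param path output file; per-class probability columns are appended
#' @return `path`, invisibly
#' @export
write_predictions <- function(pred, path) {
  p <- attr(pred, "probabilities")
  df <- cbind(as.data.frame(pred),
              as.data.frame(p, check.names = FALSE, row.names = NULL))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotation performance metrics
#'
#' Computes overall accuracy, per-class F1, Macro F1 (unweighted mean
#' over classes present in truth or predictions; classes absent from
#' both are excluded unless `include_absent = TRUE`), and the Macro F1
#' of the binary known-vs-unknown task used to judge open-set rejection.
#'
#' @param predicted character vector of predicted labels (may contain
#'   `"unknown"`), or an `scpml_prediction`
#' @param truth character vector of true labels, aligned on cell order;
#'   cells of types absent from the reference should carry `"unknown"`
#' @param include_absent include classes absent from both truth and
#'   predictions (F1 = 0) in the macro average
#' @param alphabet optional class universe used when `include_absent`
#' @return list with `accuracy`, `per_class_f1`, `macro_f1`,
#'   `binary_unknown_f1`, `confusion`
#' @export
evaluate_predictions <- function(predicted, truth, include_absent = FALSE,
                                 alphabet = NULL) {
  if (inherits(predicted, "scpml_prediction")) predicted <- predicted$label
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted (", length(predicted), ") and truth (", length(truth),
         ") lengths differ")
  }
  classes <- sort(union(unique(truth), unique(predicted)))
  if (include_absent && !is.null(alphabet)) {
    classes <- sort(union(classes, alphabet))
  }
  conf <- table(factor(truth, classes), factor(predicted, classes))
  accuracy <- mean(predicted == truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1)
  present <- vapply(classes, function(cl) {
    cl %in% truth || cl %in% predicted
  }, TRUE)
  macro_classes <- if (include_absent) classes else classes[present]
  macro_f1 <- mean(f1[macro_classes])

  bin_truth <- ifelse(truth == "unknown", "unknown", "known")
  bin_pred <- ifelse(predicted == "unknown", "unknown", "known")
  bin_f1 <- vapply(c("known", "unknown"), function(cl) {
    tp <- sum(bin_pred == cl & bin_truth == cl)
    fp <- sum(bin_pred == cl & bin_truth != cl)
    fn <- sum(bin_pred != cl & bin_truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1)

  list(accuracy = accuracy, per_class_f1 = f1, macro_f1 = macro_f1,
       binary_unknown_f1 = mean(bin_f1), confusion = conf)
}

#' Write evaluation metrics as JSON
#' @param metrics result of [evaluate_predictions()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metrics <- function(metrics, path) {
  out <- metrics[c("accuracy", "macro_f1", "binary_unknown_f1")]
  out$per_class_f1 <- as.list(metrics$per_class_f1)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
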