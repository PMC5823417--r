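#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors of equal length with values in
#'   `class_names`.
#' @param class_names Ordered class labels.
#' @return A K x K integer matrix of class `hb_confusion`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1) {
    stop_ehc("y_true and y_pred must have equal positive length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(bad)) stop_ehc("unknown label(s): %s", paste(bad, collapse = ", "))
  ft <- factor(y_true, levels = class_names)
  fp <- factor(y_pred, levels = class_names)
  tab <- table(true = ft, predicted = fp)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  structure(m, class = c("hb_confusion", "matrix", "array"))
}

#' Overall accuracy from a confusion matrix
#' @param cm An `hb_confusion` (or plain square count matrix).
#' @return trace / total.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) stop_ehc("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Per-class one-vs-rest true positive rate (recall)
#' @param cm Confusion matrix.
#' @return Named vector `TP / (TP + FN)` per class; classes with no true
#'   instances yield 0 with a warning.
#' @export
per_class_tpr <- function(cm) {
  if (sum(cm) <= 0) stop_ehc("empty confusion matrix")
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, diag(cm) / rs, 0)
  if (any(rs == 0)) {
    warning("class with no true instances: TPR recorded as 0", call. = FALSE)
  }
  stats::setNames(out, rownames(cm))
}

#' Per-class one-vs-rest precision (positive predictive value)
#' @param cm Confusion matrix.
#' @return Named vector `TP / (TP + FP)` per class; classes never predicted
#'   yield 0 with a warning.
#' @export
per_class_precision <- function(cm) {
  if (sum(cm) <= 0) stop_ehc("empty confusion matrix")
  cs <- colSums(cm)
  out <- ifelse(cs > 0, diag(cm) / cs, 0)
  if (any(cs == 0)) {
    warning("class never predicted: precision recorded as 0", call. = FALSE)
  }
  stats::setNames(out, rownames(cm))
}

#' Per-class F-measure and support-weighted aggregates
#'
#' F per class is `2 P R / (P + R)` (harmonic mean of precision and recall,
#' 0 where both are 0).  Aggregates of accuracy-companion metrics are
#' weighted by class support (true-instance counts), the convention under
#' which the aggregate TPR equals the overall accuracy.
#'
#' @param cm Confusion matrix.
#' @return List: `per_class` (data frame of tpr, precision, f per class) and
#'   `weighted` (named vector of aggregate tpr, precision, f).
#' @export
f_measure <- function(cm) {
  tpr <- suppressWarnings(per_class_tpr(cm))
  prec <- suppressWarnings(per_class_precision(cm))
  f <- ifelse(tpr + prec > 0, 2 * prec * tpr / (prec + tpr), 0)
  w <- rowSums(cm) / sum(cm)
  list(per_class = data.frame(class = rownames(cm), tpr = tpr,
                              precision = prec, f = f, row.names = NULL),
       weighted = c(tpr = sum(w * tpr), precision = sum(w * prec),
                    f = sum(w * f)))
}

#' Cohen's kappa statistic
#'
#' Chance-corrected agreement between predictions and true classes:
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (the accuracy) and
#' expected agreement `p_e = sum_i row_i * col_i / total^2`.  Returns 0 when
#' `p_e = 1`; values below 0 (worse than chance) are passed through with a
#' warning.
#'
#' @param cm Confusion matrix.
#' @return Kappa value (1 = complete agreement).
#' @export
kappa_statistic <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) stop_ehc("empty confusion matrix")
  po <- accuracy(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (pe >= 1) return(0)
  k <- (po - pe) / (1 - pe)
  if (k < 0) warning("kappa below 0: agreement worse than chance", call. = FALSE)
  k
}

#' Probabilistic mean absolute error and root mean squared error
#'
#' Error of predicted class-probability vectors against one-hot true labels:
#' MAE is the mean over records and classes of `|p - t|` (absolute errors,
#' not squared before averaging); RMSE squares the differences before
#' averaging, then takes the square root, giving more weight to large
#' errors.  By Jensen's inequality MAE <= RMSE always.
#'
#' @param y_true True labels.
#' @param prob Matrix of class probabilities (records x classes, columns in
#'   `class_names` order), each row summing to 1.
#' @param class_names Ordered class labels.
#' @return List with `mae` and `rmse` in `[0, 1]`.
#' @export
probabilistic_errors <- function(y_true, prob, class_names) {
  prob <- as.matrix(prob)
  if (nrow(prob) != length(y_true) || ncol(prob) != length(class_names)) {
    stop_ehc("probability matrix must be records x classes")
  }
  if (any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop_ehc("probability rows must sum to 1")
  }
  t1 <- matrix(0, nrow(prob), ncol(prob))
  t1[cbind(seq_len(nrow(prob)), match(as.character(y_true), class_names))] <- 1
  err <- prob - t1
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Full seven-metric evaluation report
#'
#' Bundles the confusion matrix with the seven metrics used to compare the
#' model variants: accuracy, true positive rate, precision, F-measure
#' (support-weighted aggregates, per-class values retained), Cohen's kappa,
#' and the probabilistic MAE/RMSE.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param prob Predicted class-probability matrix.
#' @param class_names Ordered class labels.
#' @param model_tag Label identifying the model variant.
#' @param seed Seed used to produce the predictions (bookkeeping).
#' @return An `hb_metrics` list.
#' @export
metrics_report <- function(y_true, y_pred, prob, class_names,
                           model_tag = "", seed = NA_integer_) {
  cm <- confusion_matrix(y_true, y_pred, class_names)
  fm <- f_measure(cm)
  pe <- probabilistic_errors(y_true, prob, class_names)
  structure(list(
    confusion = cm,
    accuracy = accuracy(cm),
    tpr = unname(fm$weighted["tpr"]),
    precision = unname(fm$weighted["precision"]),
    f_measure = unname(fm$weighted["f"]),
    kappa = kappa_statistic(cm),
    mae = pe$mae,
    rmse = pe$rmse,
    per_class = fm$per_class,
    model_tag = model_tag,
    seed = seed
  ), class = "hb_metrics")
}

metric_names <- function() {
  c("accuracy", "tpr", "precision", "f_measure", "kappa", "mae", "rmse")
}

#' @export
as.data.frame.hb_metrics <- function(x, ...) {
  data.frame(metric = metric_names(),
             value = vapply(metric_names(), function(m) x[[m]], 0),
             row.names = NULL)
}

#' @export
print.hb_metrics <- function(x, ...) {
  cat(sprintf("<hb_metrics> %s\n", x$model_tag))
  df <- as.data.frame(x)
  cat(paste(sprintf("  %-10s %6.2f%%", df$metric, 100 * df$value),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report An `hb_metrics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  obj <- list(model_tag = report$model_tag, seed = report$seed,
              metrics = stats::setNames(
                lapply(metric_names(), function(m) report[[m]]), metric_names()),
              per_class = report$per_class,
              confusion = list(class_names = rownames(report$confusion),
                               counts = unclass(report$confusion)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a metrics report written by [save_report()]
#' @param path JSON path.
#' @return A list with the stored metrics (not a full `hb_metrics`).
#' @export
load_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
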