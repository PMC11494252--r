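# Confusion matrices, precision/recall/F1 (per class, macro, weighted), and
# model comparison tables.

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 P R / (P + R)`, with 0 when `P + R = 0`. Vectorized; inputs and
#' output are on the same scale (percent in, percent out).
#'
#' @param precision,recall Numeric vectors.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Build a confusion matrix
#'
#' Counts with true classes as rows and predicted classes as columns, plus a
#' row-percentage view (each nonempty row sums to 100).
#'
#' @param y_true,y_pred Equal-length label vectors over `class_order`.
#' @param class_order Class ordering (default [class_levels()]).
#' @return An object of class `confusion_matrix`: list with `classes`,
#'   `counts`, `percent`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_order = class_levels()) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown) > 0)
    stop("label(s) outside class_order: ", paste(unknown, collapse = ", "))
  tf <- factor(y_true, levels = class_order)
  pf <- factor(y_pred, levels = class_order)
  counts <- unclass(table(true = tf, predicted = pf))
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs > 0, rs, 1) * 100
  structure(list(classes = class_order, counts = counts, percent = percent),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true class, columns = predicted):\n")
  print(x$counts)
  cat("\nRow percentages:\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision = TP / column sum, recall = TP / row sum,
#' F1 = harmonic mean of the two; all in percent. Macro averages treat the
#' classes as equally important; weighted averages weight by class support
#' (true-row totals). Zero denominators yield 0 and are flagged.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`: list with `per_class`
#'   (data.frame class/precision/recall/f1/support), `macro`, `weighted`,
#'   `accuracy` (all percent), and `zero_denominator` flags.
#' @export
precision_recall_f1 <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  tp <- diag(counts)
  col_sum <- colSums(counts)
  row_sum <- rowSums(counts)
  precision <- ifelse(col_sum > 0, tp / col_sum, 0) * 100
  recall <- ifelse(row_sum > 0, tp / row_sum, 0) * 100
  f1 <- f1_score(precision, recall)
  support <- row_sum
  total <- sum(counts)
  wts <- if (total > 0) support / total else rep(0, length(support))
  per_class <- data.frame(
    class = cm$classes, precision = precision, recall = recall, f1 = f1,
    support = as.integer(support), row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      per_class = per_class,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      weighted = c(precision = sum(wts * precision),
                   recall = sum(wts * recall), f1 = sum(wts * f1)),
      accuracy = if (total > 0) sum(tp) / total * 100 else 0,
      zero_denominator = cm$classes[col_sum == 0 | row_sum == 0]
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  tab <- x$per_class
  tab[, 2:4] <- round(tab[, 2:4], 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Macro avg:    P %.2f  R %.2f  F1 %.2f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("Weighted avg: P %.2f  R %.2f  F1 %.2f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

#' Evaluate a fitted model on the holdout set
#'
#' Predicts the holdout rows (already normalized with the train-fitted
#' parameters) and computes the confusion matrix and metrics report.
#'
#' @param model A [train_model()] fit.
#' @param test_rows Nonempty data.frame with feature columns and `Class`.
#' @return List with `metrics` ([precision_recall_f1()] report) and
#'   `confusion` ([confusion_matrix()]).
#' @export
evaluate_holdout <- function(model, test_rows) {
  if (is.null(test_rows) || nrow(test_rows) == 0)
    stop("empty holdout test set")
  pred <- predict(model, test_rows)
  cm <- confusion_matrix(test_rows$Class, pred, class_order = model$classes)
  list(metrics = precision_recall_f1(cm), confusion = cm)
}

#' Compare models across cross-validation and holdout metrics
#'
#' Builds a CV accuracy table (mean and SD per model), a holdout table with
#' per-class precision/recall/F1 plus macro and weighted average rows per
#' model, and a ranking of the models by weighted holdout F1.
#'
#' @param reports Named list; each element a list with `cv` (a
#'   [cross_validate()] result, optional) and `metrics` (a
#'   [precision_recall_f1()] report).
#' @return List with `cv_table`, `holdout_table`, `ranking` (model names in
#'   decreasing weighted-F1 order).
#' @export
compare_models <- function(reports) {
  if (length(reports) == 0) stop("need at least one model report")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("reports must be a named list")
  cv_rows <- lapply(names(reports), function(nm) {
    cv <- reports[[nm]]$cv
    if (is.null(cv)) return(NULL)
    data.frame(model = nm,
               cv_mean_accuracy = cv$mean_accuracy * 100,
               cv_sd_accuracy = cv$sd_accuracy * 100,
               stringsAsFactors = FALSE)
  })
  cv_table <- do.call(rbind, cv_rows)
  if (!is.null(cv_table)) {
    cv_table <- cv_table[order(-cv_table$cv_mean_accuracy), , drop = FALSE]
    rownames(cv_table) <- NULL
  }

  holdout_rows <- lapply(names(reports), function(nm) {
    m <- reports[[nm]]$metrics
    per <- m$per_class
    rbind(
      data.frame(model = nm, label = per$class, precision = per$precision,
                 recall = per$recall, f1 = per$f1,
                 stringsAsFactors = FALSE),
      data.frame(model = nm, label = "macro average",
                 precision = m$macro["precision"], recall = m$macro["recall"],
                 f1 = m$macro["f1"], stringsAsFactors = FALSE),
      data.frame(model = nm, label = "weighted average",
                 precision = m$weighted["precision"],
                 recall = m$weighted["recall"], f1 = m$weighted["f1"],
                 stringsAsFactors = FALSE)
    )
  })
  holdout_table <- do.call(rbind, holdout_rows)
  rownames(holdout_table) <- NULL

  wf1 <- vapply(reports, function(r) unname(r$metrics$weighted["f1"]),
                numeric(1))
  list(cv_table = cv_table, holdout_table = holdout_table,
       ranking = names(sort(wf1, decreasing = TRUE)))
}
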