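#' Confusion matrix of structure classifications
#'
#' Rows are ground-truth classes (including the analysis-only `"Other"`
#' class), columns are predicted classes. `"Other"` is never a prediction, so
#' its column is structurally all-zero.
#'
#' @param truth Ground-truth labels (class ids or canonical names).
#' @param predicted Predicted labels, same length; must be trainable classes.
#' @param tax The `rtn_taxonomy` defining the label set.
#' @return An `rtn_confusion`: list with the integer `counts` matrix and the
#'   taxonomy.
#' @export
confusion <- function(truth, predicted, tax = default_taxonomy()) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  levels_all <- tax$classes$canonical_name
  truth <- to_canonical(truth, tax)
  predicted <- to_canonical(predicted, tax)
  trainable <- trainable_classes(tax)$canonical_name
  if (!all(predicted %in% trainable)) {
    stop("predicted labels must be trainable classes", call. = FALSE)
  }
  counts <- table(factor(truth, levels = levels_all),
                  factor(predicted, levels = levels_all))
  counts <- matrix(as.integer(counts), nrow = length(levels_all),
                   dimnames = list(truth = levels_all, predicted = levels_all))
  structure(list(counts = counts, taxonomy = tax), class = "rtn_confusion")
}

to_canonical <- function(x, tax) {
  if (is.numeric(x)) {
    nm <- tax$classes$canonical_name[match(as.integer(x), tax$classes$class_id)]
  } else {
    nm <- as.character(x)
  }
  if (anyNA(nm) || !all(nm %in% tax$classes$canonical_name)) {
    stop("labels outside the taxonomy", call. = FALSE)
  }
  nm
}

#' @export
print.rtn_confusion <- function(x, ...) {
  total <- sum(x$counts)
  cat(sprintf("<rtn_confusion: %d structures, accuracy %.4f>\n", total,
              sum(diag(x$counts)) / total))
  invisible(x)
}

#' Row-normalized view of a confusion matrix
#' @param x An `rtn_confusion`.
#' @return Numeric matrix with rows summing to 1 (0 rows left at 0).
#' @export
normalize_confusion <- function(x) {
  stopifnot(inherits(x, "rtn_confusion"))
  rs <- rowSums(x$counts)
  sweep(x$counts, 1, pmax(rs, 1), "/")
}

#' Classification report: per-class and averaged metrics
#'
#' Computes per-class precision, recall and F1 (0 where undefined, with a
#' note), unweighted accuracy, macro (unweighted mean over classes with
#' ground-truth support) and class-frequency-weighted averages. With
#' `cleaned = TRUE` the analysis-only `"Other"` row (structures whose true
#' class is outside the training nomenclature, hence necessarily
#' misclassified) is dropped before computing metrics.
#'
#' @param x An `rtn_confusion`.
#' @param cleaned Drop the `"Other"` ground-truth row first?
#' @return An `rtn_report`: list with the `per_class` tibble, `accuracy`,
#'   `accuracy_pct` (one decimal, round-half-even), `macro` and `weighted`
#'   metric rows, `n_total`, `n_misclassified` and `notes`.
#' @export
classification_report <- function(x, cleaned = FALSE) {
  stopifnot(inherits(x, "rtn_confusion"))
  counts <- x$counts
  if (cleaned) {
    other <- x$taxonomy$classes$canonical_name[x$taxonomy$classes$category == "other"]
    keep <- !(rownames(counts) %in% other)
    counts <- counts[keep, , drop = FALSE]
  }
  if (sum(counts) == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(counts)
  common <- intersect(classes, colnames(counts))
  tp <- vapply(common, function(cl) counts[cl, cl], numeric(1))
  tp <- tp[match(classes, common)]
  tp[is.na(tp)] <- 0
  support <- rowSums(counts)
  pred_n <- colSums(counts)[match(classes, colnames(counts))]
  pred_n[is.na(pred_n)] <- 0
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  notes <- character(0)
  if (any(pred_n == 0 & support > 0)) {
    notes <- c(notes, "precision undefined (no predictions) for some classes; reported 0")
  }
  per_class <- tibble::tibble(class = classes, n = as.integer(unname(support)),
                              precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1))
  active <- support > 0
  total <- sum(counts)
  correct <- sum(tp)
  freq <- support[active] / sum(support[active])
  report <- list(
    per_class = per_class,
    accuracy = correct / total,
    accuracy_pct = round(100 * correct / total, 1),
    n_total = as.integer(total),
    n_misclassified = as.integer(total - correct),
    macro = c(precision = mean(precision[active]), recall = mean(recall[active]),
              f1 = mean(f1[active])),
    weighted = c(precision = sum(freq * precision[active]),
                 recall = sum(freq * recall[active]),
                 f1 = sum(freq * f1[active])),
    cleaned = cleaned,
    notes = notes
  )
  structure(report, class = "rtn_report")
}

#' @export
print.rtn_report <- function(x, ...) {
  cat(sprintf("<rtn_report%s: n=%d, misclassified=%d, accuracy %.4f (%.1f%%), weighted F1 %.4f>\n",
              if (x$cleaned) " (cleaned)" else "", x$n_total, x$n_misclassified,
              x$accuracy, x$accuracy_pct, x$weighted["f1"]))
  invisible(x)
}

#' Quality-control performance report
#'
#' Treats "structure was misclassified" as the positive condition and "a QC
#' flag was raised" as the positive test, and reports the standard binary
#' metrics. Undefined precision/recall (no flags or no errors) are reported
#' as 0 with a note.
#'
#' @param flagged Logical vector: QC flag raised per structure.
#' @param misclassified Logical vector, same length: structure misclassified.
#' @return An `rtn_qc_report`: list of `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`, `accuracy`, `notes`.
#' @export
qc_report <- function(flagged, misclassified) {
  if (length(flagged) != length(misclassified)) {
    stop("flagged and misclassified must have equal length", call. = FALSE)
  }
  tp <- sum(flagged & misclassified)
  fp <- sum(flagged & !misclassified)
  fn <- sum(!flagged & misclassified)
  tn <- sum(!flagged & !misclassified)
  notes <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    notes <- c(notes, "precision undefined (no flags); reported 0"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    notes <- c(notes, "recall undefined (no misclassifications); reported 0"); 0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(flagged), notes = notes),
            class = "rtn_qc_report")
}

#' @export
print.rtn_qc_report <- function(x, ...) {
  cat(sprintf("<rtn_qc_report: TP=%d FP=%d FN=%d TN=%d | precision %.3f recall %.3f F1 %.3f accuracy %.3f>\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Evaluate pipeline results against a ground-truth table
#'
#' Joins a results table (as from [rename_cohort()]) with a truth table
#' (`subject_id`, `roi_number`, `true_class`) and computes the confusion
#' matrix and classification report.
#'
#' @param results Tibble with `subject_id`, `roi_number`, `predicted_class`.
#' @param truth Tibble with `subject_id`, `roi_number`, `true_class`.
#' @param tax Taxonomy.
#' @param cleaned Drop `"Other"` ground truth before metrics?
#' @return List of `confusion` and `report`; also returns the joined tibble.
#' @export
evaluate_results <- function(results, truth, tax = default_taxonomy(),
                             cleaned = FALSE) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(results), tibble::as_tibble(truth),
    by = c("subject_id", "roi_number"))
  if (nrow(joined) == 0) stop("no overlapping structures to evaluate", call. = FALSE)
  cm <- confusion(joined$true_class, joined$predicted_class, tax)
  list(confusion = cm, report = classification_report(cm, cleaned = cleaned),
       joined = joined)
}
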