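#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classification report
#' @param x An `rtn_report`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @method tidy rtn_report
#' @export
tidy.rtn_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of a classification report
#' @param x An `rtn_report`.
#' @param ... Unused.
#' @return One-row tibble with accuracy and averaged metrics.
#' @method glance rtn_report
#' @export
glance.rtn_report <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_misclassified = x$n_misclassified,
    accuracy = x$accuracy, accuracy_pct = x$accuracy_pct,
    macro_precision = x$macro["precision"], macro_recall = x$macro["recall"],
    macro_f1 = x$macro["f1"],
    weighted_precision = x$weighted["precision"],
    weighted_recall = x$weighted["recall"], weighted_f1 = x$weighted["f1"],
    cleaned = x$cleaned)
}

#' Tidy a confusion matrix into long form
#' @param x An `rtn_confusion`.
#' @param ... Unused.
#' @return Tibble `truth`, `predicted`, `n`.
#' @method tidy rtn_confusion
#' @export
tidy.rtn_confusion <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n",
                            stringsAsFactors = FALSE)
  tibble::as_tibble(stats::setNames(df, c("truth", "predicted", "n")))
}

#' Per-fold summary of a trained ensemble
#' @param x An `rtn_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy rtn_ensemble
#' @export
tidy.rtn_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$folds, function(f) {
    tibble::tibble(fold_index = f$fold_index,
                   validation_weighted_accuracy = f$validation_weighted_accuracy,
                   final_learning_rate = f$log$learning_rate[nrow(f$log)],
                   final_train_loss = f$log$train_loss[nrow(f$log)])
  }))
}

#' One-row summary of a trained ensemble
#' @param x An `rtn_ensemble`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance rtn_ensemble
#' @export
glance.rtn_ensemble <- function(x, ...) {
  accs <- vapply(x$folds, `[[`, numeric(1), "validation_weighted_accuracy")
  tibble::tibble(n_folds = length(x$folds),
                 n_classes = length(x$folds[[1]]$class_order),
                 mean_val_weighted_accuracy = mean(accs),
                 min_val_weighted_accuracy = min(accs),
                 max_val_weighted_accuracy = max(accs),
                 epochs = x$config$epochs,
                 input_resolution = x$config$input_resolution)
}

#' Tidy a QC performance report
#' @param x An `rtn_qc_report`.
#' @param ... Unused.
#' @return One-row tibble of counts and metrics.
#' @method tidy rtn_qc_report
#' @export
tidy.rtn_qc_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 accuracy = x$accuracy)
}
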