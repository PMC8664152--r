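#' Plot a confusion matrix
#'
#' Heat-map of the (optionally row-normalized) confusion matrix, ground
#' truth on rows and predictions on columns.
#'
#' @param object An `rtn_confusion`.
#' @param normalize Show row-normalized fractions (default) or raw counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtn_confusion
#' @export
autoplot.rtn_confusion <- function(object, normalize = TRUE, ...) {
  mat <- if (normalize) normalize_confusion(object) else object$counts
  df <- as.data.frame.table(mat, responseName = "value",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("truth", "predicted")
  lev <- rownames(object$counts)
  df$truth <- factor(df$truth, levels = rev(lev))
  df$predicted <- factor(df$predicted, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 name = if (normalize) "fraction" else "count") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot ensemble training curves
#'
#' Validation weighted accuracy (and learning rate) per epoch for each fold.
#'
#' @param object An `rtn_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtn_ensemble
#' @export
autoplot.rtn_ensemble <- function(object, ...) {
  logs <- dplyr::bind_rows(lapply(object$folds, function(f) {
    dplyr::mutate(f$log, fold = factor(f$fold_index))
  }))
  ggplot2::ggplot(logs, ggplot2::aes(x = .data$epoch,
                                     y = .data$val_weighted_accuracy,
                                     colour = .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "validation weighted accuracy") +
    ggplot2::theme_minimal()
}

#' Display the four input channels of a feature sample
#'
#' Facetted raster view of the transversal/coronal/sagittal projections and
#' the AddMap context channel for one feature-store row.
#'
#' @param store An `rtn_feature_store`.
#' @param row Row index into the store.
#' @return A ggplot object.
#' @export
plot_feature_sample <- function(store, row = 1L) {
  arr <- store$channels[[row]]
  ch_names <- c("transversal", "coronal", "sagittal", "AddMap")
  dfs <- lapply(1:4, function(ch) {
    m <- arr[, , ch]
    data.frame(row = rep(seq_len(nrow(m)), ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m),
               channel = factor(ch_names[ch], levels = ch_names))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = store$original_name[row], x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
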