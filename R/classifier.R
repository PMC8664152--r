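#' Training configuration for the classification ensemble
#'
#' Defaults follow the reference training recipe: batch size 72, 100 epochs,
#' Adam with learning rate 0.001 and a plateau schedule multiplying the rate
#' by 0.2 after 10 epochs without strict improvement of the validation
#' weighted accuracy, 10-fold subject-level cross-validation, 256-pixel input
#' resolution. `hidden_units` parameterizes the built-in backbone (see
#' [backbone_mlp()]); no early stopping is used — the final-epoch model of
#' every fold is kept.
#'
#' @param backbone_id Registered backbone identifier (currently `"mlp"`).
#' @param batch_size,epochs,learning_rate,lr_decay_factor,lr_patience_epochs
#'   Optimizer schedule parameters.
#' @param n_folds Number of cross-validation folds (>= 2).
#' @param input_resolution Input image side length in pixels.
#' @param hidden_units Integer vector of hidden-layer widths.
#' @param seed Integer seed governing fold splits, weight init and batching.
#' @return An `rtn_training_config` list.
#' @export
training_config <- function(backbone_id = "mlp", batch_size = 72L, epochs = 100L,
                            learning_rate = 0.001, lr_decay_factor = 0.2,
                            lr_patience_epochs = 10L, n_folds = 10L,
                            input_resolution = 256L, hidden_units = 64L,
                            seed = 1L) {
  if (!(lr_decay_factor > 0 && lr_decay_factor < 1)) {
    stop("lr_decay_factor must be in (0, 1)", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(backbone_id = backbone_id, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 n_folds = as.integer(n_folds),
                 input_resolution = as.integer(input_resolution),
                 hidden_units = as.integer(hidden_units),
                 seed = as.integer(seed)),
            class = "rtn_training_config")
}

#' Subject-level cross-validation splits
#'
#' Shuffles the subject ids deterministically under `seed` and deals them
#' round-robin into `n_folds` validation sets, so every subject appears in
#' exactly one validation set and train/validation sets are disjoint within
#' each fold.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List of `n_folds` splits, each
#'   `list(fold_index, train_subjects, validation_subjects)`.
#' @export
split_subjects <- function(subject_ids, n_folds, seed) {
  subject_ids <- unique(as.character(subject_ids))
  n_folds <- as.integer(n_folds)
  if (length(subject_ids) < n_folds) {
    stop("fewer subjects than folds", call. = FALSE)
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(subject_ids))
  assignment <- rep_len(seq_len(n_folds), length(shuffled))
  lapply(seq_len(n_folds), function(f) {
    val <- shuffled[assignment == f]
    list(fold_index = f,
         train_subjects = sort(setdiff(subject_ids, val)),
         validation_subjects = sort(val))
  })
}

#' Weighted categorical cross-entropy
#'
#' `loss = -w[true] * log(p[true] + eps)` with a small epsilon guard inside
#' the logarithm. Used per-sample during backbone training; exposed for
#' testing and for custom backbones.
#'
#' @param predicted_probs Probability vector summing to 1 (within 1e-5).
#' @param true_class 1-based index of the true class within the vector.
#' @param weights Positive per-class weight vector (same length), or a single
#'   weight for the true class.
#' @param eps Numerical guard (default 1e-12).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(predicted_probs, true_class, weights,
                                   eps = 1e-12) {
  if (any(predicted_probs < 0)) stop("negative probabilities", call. = FALSE)
  if (abs(sum(predicted_probs) - 1) > 1e-5) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  w <- if (length(weights) == 1) weights else weights[true_class]
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  -w * log(predicted_probs[true_class] + eps)
}

# ---- backbone contract ----------------------------------------------------
# A backbone is a list of three functions:
#   init(n_in, n_classes, hidden_units, seed) -> params
#   forward(params, X)        -> n x K probability matrix (softmax output)
#   train_step(params, state, X, Y1hot, w_row, lr) -> list(params, state, loss)
# The built-in "mlp" backbone is a compact fully-connected softmax network
# trained with Adam; deeper architectures can be registered under new ids.

#' Reference fully-connected backbone
#'
#' A compact multilayer perceptron over the flattened 4-channel input
#' (ReLU hidden layers, He initialization, softmax output) trained with Adam
#' on the weighted categorical cross-entropy. It is the desk-scale default:
#' the surrounding ensemble, voting and QC machinery is backbone-agnostic,
#' and heavier convolutional backbones can be plugged in through the same
#' contract.
#'
#' @return A backbone object (list of `init`, `forward`, `train_step`).
#' @export
backbone_mlp <- function() {
  init <- function(n_in, n_classes, hidden_units, seed) {
    sizes <- c(n_in, hidden_units, n_classes)
    withr::with_seed(as.integer(seed), {
      layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
        fan_in <- sizes[l]
        list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                        fan_in, sizes[l + 1L]),
             b = numeric(sizes[l + 1L]))
      })
    })
    layers
  }
  fwd_cache <- function(params, X) {
    acts <- list(X)
    n_layers <- length(params)
    for (l in seq_len(n_layers)) {
      Z <- acts[[l]] %*% params[[l]]$W
      Z <- sweep(Z, 2, params[[l]]$b, "+")
      acts[[l + 1L]] <- if (l < n_layers) pmax(Z, 0) else Z
    }
    acts
  }
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  forward <- function(params, X) {
    acts <- fwd_cache(params, X)
    softmax(acts[[length(acts)]])
  }
  train_step <- function(params, state, X, Y1hot, w_row, lr) {
    n <- nrow(X)
    acts <- fwd_cache(params, X)
    P <- softmax(acts[[length(acts)]])
    eps <- 1e-12
    loss <- -sum(w_row * log(rowSums(P * Y1hot) + eps)) / n
    # gradient at logits of the weighted CE, averaged over the batch
    delta <- (w_row * (P - Y1hot)) / n
    n_layers <- length(params)
    grads <- vector("list", n_layers)
    for (l in rev(seq_len(n_layers))) {
      grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
      if (l > 1L) {
        delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
      }
    }
    if (is.null(state)) {
      state <- list(t = 0, m = rapply(grads, function(g) g * 0, how = "replace"),
                    v = rapply(grads, function(g) g * 0, how = "replace"))
    }
    state$t <- state$t + 1
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    for (l in seq_len(n_layers)) {
      for (p in c("W", "b")) {
        g <- grads[[l]][[p]]
        state$m[[l]][[p]] <- b1 * state$m[[l]][[p]] + (1 - b1) * g
        state$v[[l]][[p]] <- b2 * state$v[[l]][[p]] + (1 - b2) * g * g
        mhat <- state$m[[l]][[p]] / (1 - b1^state$t)
        vhat <- state$v[[l]][[p]] / (1 - b2^state$t)
        params[[l]][[p]] <- params[[l]][[p]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    list(params = params, state = state, loss = loss)
  }
  list(id = "mlp", init = init, forward = forward, train_step = train_step)
}

get_backbone <- function(backbone_id) {
  switch(backbone_id,
         mlp = backbone_mlp(),
         stop("unknown backbone: ", backbone_id, call. = FALSE))
}

store_design <- function(store) {
  X <- t(vapply(store$channels, as.vector,
                numeric(length(store$channels[[1]]))))
  X
}

# inverse-class-frequency weighted ("balanced") accuracy
weighted_accuracy <- function(true_class, predicted_class) {
  counts <- table(true_class)
  w <- sum(counts) / (length(counts) * as.numeric(counts))
  wi <- w[match(as.character(true_class), names(counts))]
  sum(wi * (true_class == predicted_class)) / sum(wi)
}

#' Train one cross-validation fold
#'
#' Trains the configured backbone on the fold's training subjects with
#' class-balanced weighted categorical cross-entropy and the plateau learning
#' rate schedule (rate multiplied by `lr_decay_factor` after
#' `lr_patience_epochs` epochs without strict improvement of validation
#' weighted accuracy). Class weights are computed on the fold's own training
#' subjects. Samples with non-trainable (`"other"`) classes are excluded.
#' Classes absent from the fold's training subjects stay in the output layer
#' with a warning.
#'
#' @param store An `rtn_feature_store` with ground-truth `class_id`.
#' @param split One element of [split_subjects()].
#' @param config An [rtnamer::training_config()].
#' @param tax The `rtn_taxonomy` the labels refer to.
#' @return An `rtn_trained_fold`: backbone parameters, `class_order`
#'   (class ids of the output layer), `validation_weighted_accuracy`, and a
#'   per-epoch `log` tibble (epoch, learning rate, training loss, validation
#'   weighted accuracy).
#' @export
train_fold <- function(store, split, config, tax = default_taxonomy()) {
  trainable <- trainable_classes(tax)
  class_order <- trainable$class_id
  usable <- store$class_id %in% class_order
  store <- store[usable, , drop = FALSE]
  missing_subj <- setdiff(c(split$train_subjects, split$validation_subjects),
                          unique(store$subject_id))
  if (length(missing_subj) > 0) {
    stop("feature store lacks subjects: ", paste(missing_subj, collapse = ", "),
         call. = FALSE)
  }
  tr <- store$subject_id %in% split$train_subjects
  va <- store$subject_id %in% split$validation_subjects
  y_tr <- match(store$class_id[tr], class_order)
  y_va <- match(store$class_id[va], class_order)
  absent <- setdiff(class_order, store$class_id[tr])
  if (length(absent) > 0) {
    warning("class(es) absent from fold training subjects: ",
            paste(trainable$canonical_name[match(absent, class_order)],
                  collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(y_tr, levels = seq_along(class_order)))
  w_class <- numeric(length(class_order))
  present <- as.numeric(counts) > 0
  w_class[present] <- compute_class_weights(as.numeric(counts)[present])

  X_all <- store_design(store)
  X_tr <- X_all[tr, , drop = FALSE]
  X_va <- X_all[va, , drop = FALSE]
  rm(X_all)

  backbone <- get_backbone(config$backbone_id)
  K <- length(class_order)
  fold_seed <- config$seed * 131L + split$fold_index
  params <- backbone$init(ncol(X_tr), K, config$hidden_units, fold_seed)

  Y1hot <- matrix(0, length(y_tr), K)
  Y1hot[cbind(seq_along(y_tr), y_tr)] <- 1
  w_row <- w_class[y_tr]

  state <- NULL
  lr <- config$learning_rate
  best_acc <- -Inf
  stall <- 0L
  log_rows <- vector("list", config$epochs)
  n_tr <- length(y_tr)
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(fold_seed + epoch, sample.int(n_tr))
    losses <- c()
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      step <- backbone$train_step(params, state, X_tr[idx, , drop = FALSE],
                                  Y1hot[idx, , drop = FALSE], w_row[idx], lr)
      params <- step$params
      state <- step$state
      losses <- c(losses, step$loss)
    }
    P_va <- backbone$forward(params, X_va)
    pred_va <- max.col(P_va, ties.method = "first")
    val_acc <- weighted_accuracy(y_va, pred_va)
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch, learning_rate = lr,
                                        train_loss = mean(losses),
                                        val_weighted_accuracy = val_acc)
    if (val_acc > best_acc) {
      best_acc <- val_acc
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$lr_patience_epochs) {
        lr <- lr * config$lr_decay_factor
        stall <- 0L
      }
    }
  }
  log <- dplyr::bind_rows(log_rows)
  structure(list(params = params, class_order = class_order,
                 backbone_id = config$backbone_id,
                 class_weights = stats::setNames(w_class, trainable$canonical_name),
                 validation_weighted_accuracy = log$val_weighted_accuracy[config$epochs],
                 fold_index = split$fold_index, log = log),
            class = "rtn_trained_fold")
}

#' Per-class training-volume percentiles
#'
#' The 1st and 99th percentile (linear interpolation between order
#' statistics) of the pre-resampling structure volumes, per trainable class,
#' used by the volume quality-control check.
#'
#' @param store An `rtn_feature_store` with ground-truth labels.
#' @param tax The taxonomy; every trainable class must have at least one
#'   sample.
#' @param probs Percentile pair (default `c(0.01, 0.99)`).
#' @return Tibble `class_id`, `canonical_name`, `n`, `p1`, `p99` (cm^3).
#' @export
volume_percentiles <- function(store, tax = default_taxonomy(),
                               probs = c(0.01, 0.99)) {
  trainable <- trainable_classes(tax)
  out <- lapply(seq_len(nrow(trainable)), function(i) {
    v <- store$volume_cm3[!is.na(store$class_id) &
                            store$class_id == trainable$class_id[i]]
    if (length(v) == 0) {
      stop("no training samples for class ", trainable$canonical_name[i],
           call. = FALSE)
    }
    q <- stats::quantile(v, probs = probs, type = 7, names = FALSE)
    tibble::tibble(class_id = trainable$class_id[i],
                   canonical_name = trainable$canonical_name[i],
                   n = length(v), p1 = q[1], p99 = q[2])
  })
  dplyr::bind_rows(out)
}

#' Train the full cross-validation ensemble
#'
#' Splits subjects into `config$n_folds` folds, trains one backbone per fold,
#' and bundles the folds with the taxonomy snapshot, the per-class
#' training-volume percentiles and the AddMap configuration into the ensemble
#' used at inference time.
#'
#' @inheritParams train_fold
#' @param config A [training_config()].
#' @param addmap An [addmap_config()] snapshot (stored for provenance).
#' @return An `rtn_ensemble` object.
#' @export
train_ensemble <- function(store, config = training_config(),
                           tax = default_taxonomy(), addmap = addmap_config()) {
  splits <- split_subjects(unique(store$subject_id), config$n_folds, config$seed)
  folds <- lapply(splits, function(sp) train_fold(store, sp, config, tax))
  perc <- volume_percentiles(store, tax)
  structure(list(folds = folds, taxonomy = tax, volume_percentiles = perc,
                 addmap_config = addmap, config = config),
            class = "rtn_ensemble")
}

#' @export
print.rtn_ensemble <- function(x, ...) {
  accs <- vapply(x$folds, `[[`, numeric(1), "validation_weighted_accuracy")
  cat(sprintf("<rtn_ensemble: %d folds, %d classes, mean val weighted acc %.3f>\n",
              length(x$folds), length(x$folds[[1]]$class_order), mean(accs)))
  invisible(x)
}

#' Per-class failure counts on validation data
#'
#' After training, counts per class how many validation structures each fold
#' misclassified (summed over folds); the classic "difficult classes" report.
#'
#' @param ensemble An `rtn_ensemble`.
#' @param store The training `rtn_feature_store`.
#' @return Tibble `canonical_name`, `n_failed`.
#' @export
failed_structures_report <- function(ensemble, store) {
  tax <- ensemble$taxonomy
  splits <- split_subjects(unique(store$subject_id),
                           ensemble$config$n_folds, ensemble$config$seed)
  backbone <- get_backbone(ensemble$config$backbone_id)
  trainable <- trainable_classes(tax)
  fails <- stats::setNames(rep(0L, nrow(trainable)), trainable$canonical_name)
  for (f in seq_along(ensemble$folds)) {
    fold <- ensemble$folds[[f]]
    va <- store$subject_id %in% splits[[f]]$validation_subjects &
      store$class_id %in% fold$class_order
    if (!any(va)) next
    X <- store_design(store[va, , drop = FALSE])
    P <- backbone$forward(fold$params, X)
    pred <- fold$class_order[max.col(P, ties.method = "first")]
    truth <- store$class_id[va]
    wrong <- table(factor(trainable$canonical_name[match(truth[pred != truth],
                                                         trainable$class_id)],
                          levels = trainable$canonical_name))
    fails <- fails + as.integer(wrong)
  }
  tibble::tibble(canonical_name = names(fails), n_failed = as.integer(fails))
}

#' Save / load a trained ensemble
#' @param ensemble An `rtn_ensemble`.
#' @param path File path (`.rds`).
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble` the
#'   ensemble.
#' @export
write_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  readRDS(path)
}
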