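test_that("subject splits are disjoint, covering and deterministic", {
  ids <- sprintf("s%02d", 1:10)
  splits <- split_subjects(ids, 10L, seed = 4L)
  expect_length(splits, 10L)
  expect_true(all(lengths(lapply(splits, `[[`, "validation_subjects")) == 1L))
  all_val <- unlist(lapply(splits, `[[`, "validation_subjects"))
  expect_setequal(all_val, ids)
  expect_false(any(duplicated(all_val)))
  for (sp in splits) {
    expect_length(intersect(sp$train_subjects, sp$validation_subjects), 0L)
    expect_setequal(union(sp$train_subjects, sp$validation_subjects), ids)
  }
  expect_identical(splits, split_subjects(ids, 10L, seed = 4L))
  expect_false(identical(splits, split_subjects(ids, 10L, seed = 5L)))
  expect_error(split_subjects(ids[1:3], 5L, seed = 1L), "fewer subjects")
  # uneven folds stay within one subject of 1/n_folds
  sp3 <- split_subjects(sprintf("t%02d", 1:17), 3L, seed = 1L)
  sizes <- lengths(lapply(sp3, `[[`, "validation_subjects"))
  expect_true(max(sizes) - min(sizes) <= 1L)
})

test_that("weighted cross entropy has the stated closed forms", {
  expect_lt(weighted_cross_entropy(c(1, 0, 0), 1L, rep(1, 3)), 1e-10)
  for (K in c(2L, 5L, 22L)) {
    expect_equal(weighted_cross_entropy(rep(1 / K, K), 1L, rep(1, K)), log(K),
                 tolerance = 1e-9)
  }
  p <- c(0.6, 0.3, 0.1)
  expect_equal(weighted_cross_entropy(p, 2L, c(1, 2, 1)),
               2 * weighted_cross_entropy(p, 2L, rep(1, 3)))
  expect_error(weighted_cross_entropy(c(-0.1, 1.1, 0), 1L, rep(1, 3)), "negative")
  expect_error(weighted_cross_entropy(c(0.5, 0.2), 1L, rep(1, 2)), "sum to 1")
})

test_that("volume percentiles follow the linear-interpolation order-statistics convention", {
  tax <- toy_taxonomy(1L)
  store <- tibble::tibble(subject_id = "s", roi_number = 1:100,
                          original_name = "x", class_id = 0L,
                          volume_cm3 = as.numeric(sample(1:100)),
                          channels = replicate(100, array(0, c(2, 2, 4)),
                                               simplify = FALSE))
  pc <- volume_percentiles(store, tax)
  expect_equal(pc$p1, 1.99)
  expect_equal(pc$p99, 99.01)
  # independent order-statistics oracle: h = (n-1)p + 1
  v <- sort(store$volume_cm3)
  h <- (100 - 1) * 0.01 + 1
  expect_equal(pc$p1, v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)]))
  # single-sample and all-equal classes collapse to p1 == p99
  store1 <- store[1, ]
  pc1 <- volume_percentiles(store1, tax)
  expect_equal(pc1$p1, pc1$p99)
  store$volume_cm3 <- 7
  pce <- volume_percentiles(store, tax)
  expect_equal(c(pce$p1, pce$p99), c(7, 7))
  expect_error(volume_percentiles(store[0, ], tax), "no training samples")
})

test_that("training on a separable toy problem converges and is deterministic", {
  tax <- toy_taxonomy(3L)
  store <- toy_store(n_subjects = 10L, n_classes = 3L, res = 16L)
  tc <- training_config(n_folds = 2L, epochs = 20L, batch_size = 4L,
                        learning_rate = 0.01, input_resolution = 16L,
                        hidden_units = 16L, seed = 2L)
  splits <- split_subjects(unique(store$subject_id), 2L, tc$seed)
  fold <- train_fold(store, splits[[1]], tc, tax)
  expect_s3_class(fold$log, "tbl_df")
  expect_equal(nrow(fold$log), 20L)
  # loss shrinks substantially on a separable problem
  expect_lt(fold$log$train_loss[20], 0.05 * fold$log$train_loss[1])
  expect_gte(fold$validation_weighted_accuracy, 0.95)
  # determinism: identical seeds give identical trajectories
  fold2 <- train_fold(store, splits[[1]], tc, tax)
  expect_identical(fold$log, fold2$log)
  # softmax contract on the trained backbone
  backbone <- rtnamer:::get_backbone("mlp")
  P <- backbone$forward(fold$params, rtnamer:::store_design(store[1:5, ]))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-5)
  expect_true(all(P >= 0))
})

test_that("the learning-rate schedule decays by the configured factor on plateaus", {
  tax <- toy_taxonomy(2L)
  # constant features make accuracy plateau immediately
  store <- toy_store(n_subjects = 6L, n_classes = 2L, res = 8L, sd = 0)
  tc <- training_config(n_folds = 2L, epochs = 7L, batch_size = 4L,
                        input_resolution = 8L, hidden_units = 4L,
                        lr_patience_epochs = 2L, seed = 3L)
  splits <- split_subjects(unique(store$subject_id), 2L, tc$seed)
  fold <- train_fold(store, splits[[1]], tc, tax)
  lrs <- unique(fold$log$learning_rate)
  expect_true(length(lrs) > 1)
  expect_equal(lrs[2] / lrs[1], tc$lr_decay_factor)
})

test_that("weighted accuracy equals unweighted accuracy for balanced classes", {
  withr::with_seed(8, {
    truth <- rep(1:4, each = 25)
    pred <- truth
    flip <- sample(100, 17)
    pred[flip] <- (truth[flip] %% 4) + 1
    expect_equal(rtnamer:::weighted_accuracy(truth, pred), mean(truth == pred))
  })
})

test_that("ensembles bundle folds, percentiles and configuration", {
  fx <- small_pipeline_fixture()
  ens <- fx$ensemble
  expect_length(ens$folds, 2L)
  expect_equal(ens$folds[[1]]$class_order,
               trainable_classes(default_taxonomy())$class_id)
  expect_true(all(ens$volume_percentiles$p1 <= ens$volume_percentiles$p99))
  expect_setequal(ens$volume_percentiles$class_id,
                  trainable_classes(default_taxonomy())$class_id)
  # folds jointly cover the cohort without overlap
  splits <- split_subjects(unique(fx$store$subject_id), 2L, ens$config$seed)
  val_all <- unlist(lapply(splits, `[[`, "validation_subjects"))
  expect_setequal(val_all, unique(fx$store$subject_id))
  # tidy/glance accessors
  td <- tidy(ens)
  expect_equal(nrow(td), 2L)
  gl <- glance(ens)
  expect_equal(gl$n_folds, 2L)
  expect_equal(gl$mean_val_weighted_accuracy,
               mean(td$validation_weighted_accuracy))
})
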