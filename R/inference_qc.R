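#' Quality-control configuration
#'
#' Three sequential checks run for every prediction, stopping at the first
#' failure: (1) structure volume inside the per-class training-volume
#' percentile bounds, (2) at least `min_agree` of the fold models voting for
#' the final class, (3) mean probability of the final class among the
#' majority-voting models not below `prob_threshold`.
#'
#' @param min_agree Minimum number of agreeing models (default 6).
#' @param prob_threshold Mean winner-probability threshold (default 0.7;
#'   a mean strictly below this raises the flag).
#' @param volume_bounds Per-class bounds tibble (`class_id`, `p1`, `p99`),
#'   normally the ensemble's [volume_percentiles()] table.
#' @return An `rtn_qc_config` list.
#' @export
qc_config <- function(min_agree = 6L, prob_threshold = 0.7, volume_bounds) {
  if (min_agree < 1) stop("min_agree must be >= 1", call. = FALSE)
  if (!(prob_threshold > 0 && prob_threshold <= 1)) {
    stop("prob_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(min_agree = as.integer(min_agree),
                 prob_threshold = prob_threshold,
                 volume_bounds = tibble::as_tibble(volume_bounds)),
            class = "rtn_qc_config")
}

#' Default QC configuration for a trained ensemble
#'
#' Uses the ensemble's training-volume percentile table and scales the
#' vote-agreement threshold with the ensemble size: at least 6 of 10 models
#' must agree in the reference setting, generalized as
#' `ceiling(0.6 * n_folds)` for smaller ensembles.
#'
#' @param ensemble An `rtn_ensemble`.
#' @return An [qc_config()].
#' @export
default_qc_config <- function(ensemble) {
  qc_config(min_agree = max(1L, as.integer(ceiling(0.6 * length(ensemble$folds)))),
            prob_threshold = 0.7,
            volume_bounds = ensemble$volume_percentiles)
}

#' Run the ensemble on one feature sample
#'
#' @param channels A resolution x resolution x 4 channel array (one feature
#'   store row's `channels` entry).
#' @param ensemble An `rtn_ensemble`.
#' @return List with `labels` (per-fold predicted class ids) and `probs`
#'   (folds x classes probability matrix, columns in `class_order`).
#' @export
ensemble_predict <- function(channels, ensemble) {
  stopifnot(inherits(ensemble, "rtn_ensemble"))
  res <- ensemble$config$input_resolution
  if (!identical(dim(channels), c(res, res, 4L))) {
    stop(sprintf("sample resolution %s does not match ensemble input %dx%dx4",
                 paste(dim(channels), collapse = "x"), res, res), call. = FALSE)
  }
  backbone <- get_backbone(ensemble$config$backbone_id)
  x <- matrix(as.vector(channels), nrow = 1)
  probs <- t(vapply(ensemble$folds, function(fold) {
    as.numeric(backbone$forward(fold$params, x))
  }, numeric(length(ensemble$folds[[1]]$class_order))))
  class_order <- ensemble$folds[[1]]$class_order
  labels <- class_order[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs, class_order = class_order)
}

#' Majority vote over the fold models
#'
#' The final class is the modal per-fold label; ties are broken by the larger
#' summed probability over the tied classes, then by the lower class id.
#' `mean_winner_prob` averages the final class's probability over exactly the
#' folds that voted for it.
#'
#' @param labels Per-fold predicted class ids.
#' @param probs Folds x classes probability matrix.
#' @param class_order Class ids labelling the columns of `probs`.
#' @return List `final_class`, `n_agree`, `mean_winner_prob`.
#' @export
majority_vote <- function(labels, probs, class_order) {
  stopifnot(length(labels) >= 1)
  votes <- table(labels)
  top <- as.integer(names(votes)[votes == max(votes)])
  if (length(top) > 1) {
    sums <- vapply(top, function(cl) sum(probs[, match(cl, class_order)]),
                   numeric(1))
    top <- top[sums == max(sums)]
    final <- min(top)
  } else {
    final <- top
  }
  voters <- labels == final
  list(final_class = final,
       n_agree = sum(voters),
       mean_winner_prob = mean(probs[voters, match(final, class_order)]))
}

#' Apply the sequential quality-control checks
#'
#' Checks run in order volume -> vote agreement -> probability; the first
#' failure sets the flag and later checks are not evaluated, so each
#' structure carries at most one flag.
#'
#' @param prediction List with `final_class`, `n_agree`, `mean_winner_prob`
#'   (as from [majority_vote()]).
#' @param volume_cm3 The structure's pre-resampling volume.
#' @param config An [qc_config()].
#' @return One of `"pass"`, `"volume_flag"`, `"vote_flag"`,
#'   `"probability_flag"`.
#' @export
apply_qc <- function(prediction, volume_cm3, config) {
  stopifnot(inherits(config, "rtn_qc_config"))
  bounds <- config$volume_bounds[config$volume_bounds$class_id ==
                                   prediction$final_class, , drop = FALSE]
  if (nrow(bounds) != 1) {
    stop("no volume bounds configured for class ", prediction$final_class,
         call. = FALSE)
  }
  if (volume_cm3 < bounds$p1 || volume_cm3 > bounds$p99) return("volume_flag")
  if (prediction$n_agree < config$min_agree) return("vote_flag")
  if (prediction$mean_winner_prob < config$prob_threshold) return("probability_flag")
  "pass"
}

#' Classify, QC and rename one subject's structure set
#'
#' The full inference pipeline: reads the subject directory, skips
#' optimization structures (by name prefix) and empty structures entirely,
#' featurizes the rest, runs the ensemble with majority voting, applies the
#' sequential QC checks (advisory: flagged structures are still renamed), and
#' writes a renamed DICOM structure-set copy. New names are the canonical
#' class name, with the dose token from the original name appended for target
#' classes (`"<canonical_name> <doseToken>"`). Input files are never
#' modified.
#'
#' @param subject_dir Subject directory readable by [read_structure_set()].
#' @param ensemble A trained `rtn_ensemble`.
#' @param out_dir Output directory for the renamed copy (created if needed).
#' @param qc An optional [qc_config()]; defaults to the ensemble's percentile
#'   table with the standard thresholds.
#' @return List with `renamed_path`, `results` (tibble: subject_id,
#'   roi_number, original_name, predicted_class, new_name, n_agree,
#'   mean_winner_prob, volume_cm3), `qc` (results plus `flag`), and `skipped`
#'   (tibble of excluded structures with reasons).
#' @export
rename_pipeline <- function(subject_dir, ensemble, out_dir = tempfile("renamed"),
                            qc = NULL) {
  stopifnot(inherits(ensemble, "rtn_ensemble"))
  if (is.null(qc)) {
    qc <- default_qc_config(ensemble)
  }
  tax <- ensemble$taxonomy
  ss <- read_structure_set(subject_dir)
  skipped <- tibble::tibble(
    subject_id = character(0), roi_number = integer(0),
    original_name = character(0), reason = character(0))
  for (s in ss$structures) {
    reason <- if (is_optimization_structure(s$name, tax)) "optimization_structure"
      else if (s$is_empty) "empty_structure" else NA_character_
    if (!is.na(reason)) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        subject_id = ss$subject_id, roi_number = s$roi_number,
        original_name = s$name, reason = reason))
    }
  }
  samples <- featurize_structure_set(
    ss, tax, labels = NULL, resolution = ensemble$config$input_resolution,
    config = ensemble$addmap_config)

  n <- nrow(samples)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    pred <- ensemble_predict(samples$channels[[i]], ensemble)
    vote <- majority_vote(pred$labels, pred$probs, pred$class_order)
    flag <- apply_qc(vote, samples$volume_cm3[i], qc)
    cls <- class_by(tax, id = vote$final_class)
    token <- extract_dose_token(samples$original_name[i])
    new_name <- if (cls$dose_suffix_expected && !is.na(token)) {
      paste(cls$canonical_name, token)
    } else {
      cls$canonical_name
    }
    results[[i]] <- tibble::tibble(
      subject_id = samples$subject_id[i],
      roi_number = samples$roi_number[i],
      original_name = samples$original_name[i],
      predicted_class_id = vote$final_class,
      predicted_class = cls$canonical_name,
      new_name = new_name,
      n_agree = vote$n_agree,
      mean_winner_prob = vote$mean_winner_prob,
      volume_cm3 = samples$volume_cm3[i],
      flag = flag)
  }
  results <- dplyr::bind_rows(results)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  renamed_path <- file.path(out_dir, paste0(ss$subject_id, "_renamed_rtstruct.dcm"))
  plan <- stats::setNames(results$new_name, as.character(results$roi_number))
  write_renamed_copy(ss, plan, renamed_path)

  list(renamed_path = renamed_path,
       results = results[, c("subject_id", "roi_number", "original_name",
                             "predicted_class", "new_name")],
       qc = results[, c("subject_id", "roi_number", "original_name",
                        "predicted_class", "n_agree", "mean_winner_prob",
                        "volume_cm3", "flag")],
       skipped = skipped)
}

#' Run the rename pipeline over a cohort directory
#'
#' Applies [rename_pipeline()] to every subject subdirectory and binds the
#' per-subject tables.
#'
#' @param cohort_dir Directory whose subdirectories are subjects.
#' @param ensemble A trained `rtn_ensemble`.
#' @param out_dir Output directory for renamed copies.
#' @param qc Optional [qc_config()].
#' @return List of bound `results`, `qc` and `skipped` tibbles plus
#'   `renamed_paths`.
#' @export
rename_cohort <- function(cohort_dir, ensemble, out_dir = tempfile("renamed"),
                          qc = NULL) {
  dirs <- list.dirs(cohort_dir, recursive = FALSE)
  runs <- lapply(dirs, rename_pipeline, ensemble = ensemble,
                 out_dir = out_dir, qc = qc)
  list(results = dplyr::bind_rows(lapply(runs, `[[`, "results")),
       qc = dplyr::bind_rows(lapply(runs, `[[`, "qc")),
       skipped = dplyr::bind_rows(lapply(runs, `[[`, "skipped")),
       renamed_paths = vapply(runs, `[[`, character(1), "renamed_path"))
}
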