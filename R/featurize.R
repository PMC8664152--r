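#' AddMap configuration
#'
#' Weights of the context channel: every other (non-optimization, non-empty)
#' structure of the subject contributes `other_weight` to the weighted sum at
#' the target's center-of-mass slice, except the body outline which
#' contributes `body_weight`; the sum is truncated at `cap`.
#'
#' @param body_weight Weight of the body mask (default 0.1).
#' @param other_weight Weight of every other mask (default 0.2).
#' @param cap Truncation ceiling of the summed signal (default 1.0).
#' @return An `rtn_addmap_config` list.
#' @export
addmap_config <- function(body_weight = 0.1, other_weight = 0.2, cap = 1.0) {
  if (!(body_weight > 0 && body_weight <= other_weight && other_weight <= cap)) {
    stop("require 0 < body_weight <= other_weight <= cap", call. = FALSE)
  }
  structure(list(body_weight = body_weight, other_weight = other_weight, cap = cap),
            class = "rtn_addmap_config")
}

#' Orthogonal binary projections of a 3D mask
#'
#' Computes the three 2D "shadows" of the mask: along each axis the voxel
#' values met by a parallel ray are summed and the sum truncated to 1, which
#' is a max-projection. Views are returned at the native mask resolution:
#' `transversal` (rows x columns, collapsing slices), `coronal`
#' (slices x columns, collapsing rows) and `sagittal` (slices x rows,
#' collapsing columns).
#'
#' @param mask An `rtn_mask` or a 3D logical/numeric array.
#' @return List of three binary (0/1) matrices: `transversal`, `coronal`,
#'   `sagittal`.
#' @export
project <- function(mask) {
  grid <- if (inherits(mask, "rtn_mask")) mask$grid else mask
  stopifnot(length(dim(grid)) == 3)
  mode(grid) <- "numeric"
  d <- dim(grid)
  transversal <- (rowSums(grid, dims = 2) > 0) * 1L
  cs <- colSums(grid)                 # sums over rows -> (columns, slices)
  coronal <- t(cs > 0) * 1L           # (slices, columns)
  sag_cs <- colSums(aperm(grid, c(2L, 1L, 3L)))  # (rows, slices)
  sagittal <- t(sag_cs > 0) * 1L      # (slices, rows)
  list(transversal = transversal, coronal = coronal, sagittal = sagittal)
}

#' Center-of-mass axial slice of a mask
#'
#' The arithmetic mean of the foreground voxels' slice indices, rounded to
#' the nearest integer with ties rounding half up.
#'
#' @param mask An `rtn_mask` or 3D array.
#' @return Integer slice index (1-based).
#' @export
center_of_mass_slice <- function(mask) {
  grid <- if (inherits(mask, "rtn_mask")) mask$grid else mask
  d <- dim(grid)
  per_slice <- colSums(matrix(grid, nrow = d[1] * d[2], ncol = d[3]))
  total <- sum(per_slice)
  if (total == 0) stop("empty structure has no center of mass", call. = FALSE)
  as.integer(floor(sum(per_slice * seq_len(d[3])) / total + 0.5))
}

#' Compute the AddMap context channel for a target structure
#'
#' At the target's center-of-mass axial slice, every other structure's binary
#' mask is added with weight `body_weight` (the body outline) or
#' `other_weight` (all others) and the sum truncated at `cap`. The target
#' itself and all optimization structures must be excluded by the caller from
#' `others`.
#'
#' @param target `rtn_mask` of the structure of interest (non-empty).
#' @param others List of entries `list(mask = <rtn_mask>, is_body = <flag>)`;
#'   may be empty.
#' @param config An [addmap_config()].
#' @return List with the real-valued `image` (rows x columns, native
#'   resolution) and the `slice_index` used.
#' @export
compute_addmap <- function(target, others, config = addmap_config()) {
  stopifnot(inherits(config, "rtn_addmap_config"))
  k <- center_of_mass_slice(target)
  d <- dim(if (inherits(target, "rtn_mask")) target$grid else target)
  acc <- matrix(0, d[1], d[2])
  for (o in others) {
    grid <- if (inherits(o$mask, "rtn_mask")) o$mask$grid else o$mask
    w <- if (isTRUE(o$is_body)) config$body_weight else config$other_weight
    acc <- acc + w * grid[, , k]
  }
  acc <- pmin(acc, config$cap)
  list(image = acc, slice_index = k)
}

#' Nearest-neighbour resampling of a 2D image
#'
#' Each target pixel takes the value of the source pixel whose index is
#' `ceiling((i - 0.5) * S / T)` (pixel-center mapping; coordinates landing
#' exactly on a pixel boundary round half down), independently per axis.
#' Binary inputs therefore stay binary.
#'
#' @param image 2D matrix.
#' @param target_size Integer pair (rows, columns); a single integer is used
#'   for both.
#' @return Resampled matrix of the requested size.
#' @export
resize_nearest <- function(image, target_size) {
  stopifnot(is.matrix(image))
  if (length(target_size) == 1) target_size <- c(target_size, target_size)
  target_size <- as.integer(target_size)
  stopifnot(all(target_size >= 1))
  src <- dim(image)
  ri <- pmin(pmax(ceiling((seq_len(target_size[1]) - 0.5) * src[1] / target_size[1]), 1L), src[1])
  ci <- pmin(pmax(ceiling((seq_len(target_size[2]) - 0.5) * src[2] / target_size[2]), 1L), src[2])
  image[ri, ci, drop = FALSE]
}

# Assemble the 4-channel sample array (resolution x resolution x 4):
# channels 1-3 the resized projections, channel 4 the resized AddMap.
build_channels <- function(projections, addmap_image, resolution) {
  arr <- array(0, c(resolution, resolution, 4L))
  arr[, , 1L] <- resize_nearest(projections$transversal, resolution)
  arr[, , 2L] <- resize_nearest(projections$coronal, resolution)
  arr[, , 3L] <- resize_nearest(projections$sagittal, resolution)
  arr[, , 4L] <- resize_nearest(addmap_image, resolution)
  arr
}

#' Build a feature store from subject directories
#'
#' Runs the full preprocessing over a cohort: reads each subject, excludes
#' optimization structures (by name prefix rule) and empty structures from
#' both the samples and all AddMaps, rasterizes the remaining structures,
#' computes pre-resampling volumes, the three projections and the AddMap, and
#' stacks everything into a tidy feature store.
#'
#' In training mode (a `labels` table given), each structure is resolved to a
#' ground-truth `class_id` via the (subject_id, original_name) mapping, with
#' `corrections` taking precedence; unresolvable names raise an error listing
#' them. Without `labels` the store carries `class_id = NA` (inference mode).
#' The body structure for AddMap weighting is the ground-truth `Body` class
#' in training mode and the largest-volume structure otherwise.
#'
#' @param subject_dirs Character vector of subject directories.
#' @param tax An `rtn_taxonomy`.
#' @param labels Optional data frame `subject_id`, `original_name`,
#'   `class_id` (ground truth, e.g. a cohort truth table).
#' @param corrections Optional correction table from [read_corrections()].
#' @param resolution Network input resolution (pixels; default 256).
#' @param config An [addmap_config()].
#' @return An `rtn_feature_store`: tibble with columns `subject_id`,
#'   `roi_number`, `original_name`, `class_id`, `volume_cm3` and a `channels`
#'   list-column of resolution x resolution x 4 arrays.
#' @export
build_feature_store <- function(subject_dirs, tax = default_taxonomy(),
                                labels = NULL, corrections = NULL,
                                resolution = 256L, config = addmap_config()) {
  rows <- lapply(subject_dirs, function(dir) {
    ss <- read_structure_set(dir)
    featurize_structure_set(ss, tax, labels = labels, corrections = corrections,
                            resolution = resolution, config = config)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rtn_feature_store", class(out))
  attr(out, "resolution") <- as.integer(resolution)
  attr(out, "addmap_config") <- config
  out
}

#' Featurize one parsed structure set
#'
#' The per-subject worker behind [build_feature_store()]; also used at
#' inference time. See that function for the exclusion and body-resolution
#' rules.
#'
#' @inheritParams build_feature_store
#' @param ss An `rtn_structure_set`.
#' @return Tibble of samples (possibly zero rows).
#' @export
featurize_structure_set <- function(ss, tax = default_taxonomy(), labels = NULL,
                                    corrections = NULL, resolution = 256L,
                                    config = addmap_config()) {
  stopifnot(inherits(ss, "rtn_structure_set"))
  keep <- vapply(ss$structures, function(s) {
    !s$is_empty && !is_optimization_structure(s$name, tax)
  }, logical(1))
  kept <- ss$structures[keep]
  if (length(kept) == 0) {
    return(tibble::tibble(subject_id = character(0), roi_number = integer(0),
                          original_name = character(0), class_id = integer(0),
                          volume_cm3 = numeric(0), channels = list()))
  }
  masks <- lapply(kept, rasterize, geometry = ss$geometry)
  volumes <- vapply(masks, structure_volume, numeric(1), geometry = ss$geometry)
  names_kept <- vapply(kept, `[[`, character(1), "name")

  class_ids <- rep(NA_integer_, length(kept))
  if (!is.null(labels)) {
    class_ids <- resolve_labels(ss$subject_id, names_kept, labels, corrections)
  }

  body_class <- class_by(tax, name = "Body")$class_id
  if (!is.null(labels) && any(class_ids == body_class, na.rm = TRUE)) {
    is_body <- !is.na(class_ids) & class_ids == body_class
  } else {
    # inference: classes unknown up front, treat the largest structure as body
    is_body <- seq_along(kept) == which.max(volumes)
  }

  channels <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    proj <- project(masks[[i]])
    others <- lapply(setdiff(seq_along(kept), i), function(j) {
      list(mask = masks[[j]], is_body = is_body[j])
    })
    am <- compute_addmap(masks[[i]], others, config)
    channels[[i]] <- build_channels(proj, am$image, as.integer(resolution))
  }
  tibble::tibble(
    subject_id = ss$subject_id,
    roi_number = vapply(kept, `[[`, integer(1), "roi_number"),
    original_name = names_kept,
    class_id = class_ids,
    volume_cm3 = volumes,
    channels = channels
  )
}

resolve_labels <- function(subject_id, names_kept, labels, corrections) {
  labels <- as.data.frame(labels)
  sub_labels <- labels[labels$subject_id == subject_id, , drop = FALSE]
  idx <- match(names_kept, sub_labels$original_name)
  class_ids <- as.integer(sub_labels$class_id[idx])
  if (!is.null(corrections)) {
    corrections <- as.data.frame(corrections)
    sub_corr <- corrections[corrections$subject_id == subject_id, , drop = FALSE]
    cidx <- match(names_kept, sub_corr$original_name)
    hit <- !is.na(cidx)
    class_ids[hit] <- as.integer(sub_corr$corrected_class_id[cidx[hit]])
  }
  if (anyNA(class_ids)) {
    stop("unresolvable ground-truth label(s) for subject ", subject_id, ": ",
         paste(names_kept[is.na(class_ids)], collapse = ", "), call. = FALSE)
  }
  class_ids
}

#' Save / load a feature store
#'
#' The store is a plain tibble with an array list-column; persistence uses
#' R serialization.
#'
#' @param store An `rtn_feature_store`.
#' @param path File path (`.rds`).
#' @return `write_feature_store` returns `path` invisibly; `read_feature_store`
#'   the store.
#' @export
write_feature_store <- function(store, path) {
  saveRDS(store, path)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  readRDS(path)
}
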