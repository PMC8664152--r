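# Shared fixtures and independent oracles, all built in code.

# 16x16x8 grid, 1 mm voxels, pixel centers at 0.5 .. 15.5
tiny_geometry <- function(dims = c(16L, 16L, 8L), spacing = c(1, 1, 1)) {
  image_geometry(origin = spacing / 2, spacing = spacing, dims = dims)
}

square_contour <- function(x0, y0, side, z) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side), z)
}

as_struct <- function(...) list(contours = list(...))

# independent point-in-polygon oracle (mgcv::in.out), even-odd over all
# contours of one slice
oracle_fill_count <- function(contours_xy, geometry, k = 1L) {
  bnd <- do.call(rbind, lapply(contours_xy, function(p) {
    rbind(p[, 1:2, drop = FALSE], p[1, 1:2], c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  xc <- geometry$origin[1] + (seq_len(geometry$dims[2]) - 1) * geometry$spacing[1]
  yc <- geometry$origin[2] + (seq_len(geometry$dims[1]) - 1) * geometry$spacing[2]
  pts <- cbind(rep(xc, each = length(yc)), rep(yc, times = length(xc)))
  sum(mgcv::in.out(bnd, pts))
}

random_convex_polygon <- function(n_pts = 12L, cx, cy, r) {
  th <- sort(stats::runif(n_pts, 0, 2 * pi))
  rad <- stats::runif(n_pts, 0.35 * r, r)
  # convex hull of random points; guaranteed >= 3 vertices
  x <- cx + rad * cos(th); y <- cy + rad * sin(th)
  h <- grDevices::chull(x, y)
  cbind(x[h], y[h])
}

# brute-force ray-sum-then-truncate projection oracle (per-ray loops via apply)
oracle_project <- function(grid) {
  list(
    transversal = (apply(grid, c(1, 2), sum) > 0) * 1L,
    coronal = (t(apply(grid, c(2, 3), sum)) > 0) * 1L,
    sagittal = (t(apply(grid, c(1, 3), sum)) > 0) * 1L
  )
}

# small custom taxonomy for classifier unit tests
toy_taxonomy <- function(n_classes = 3L) {
  cls <- tibble::tibble(
    class_id = 0:(n_classes),
    canonical_name = c(paste0("Class", LETTERS[1:n_classes]), "Other"),
    category = c(rep("OAR", n_classes), "other"),
    dose_suffix_expected = FALSE
  )
  taxonomy(cls, optimization_prefixes = c("Tuning", "Help"))
}

# synthetic separable feature store: class c has a bright block at a
# class-specific location; volumes cluster per class
toy_store <- function(n_subjects = 9L, n_classes = 3L, res = 16L, seed = 99L,
                      sd = 0.05) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (cl in seq_len(n_classes) - 1L) {
        arr <- array(stats::rnorm(res * res * 4, 0, sd), c(res, res, 4L))
        block <- cl * 4L + seq_len(4L)
        arr[block, block, 1:3] <- arr[block, block, 1:3] + 1
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sprintf("toy%02d", s),
          roi_number = cl + 1L,
          original_name = paste0("struct", cl),
          class_id = cl,
          volume_cm3 = 50 * (cl + 1) + stats::rnorm(1, 0, 2),
          channels = list(arr))
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("rtn_feature_store", class(out))
    out
  })
}

# one small trained ensemble + its cohort, shared across tests in a file
small_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- phantom_config(seed = 11L, optimization_injection_rate = 0.2,
                          empty_structure_rate = 0.3)
    dir <- file.path(tempdir(), "rtn-small-cohort")
    coh <- generate_cohort(8, cfg, out_dir = dir,
                           scenarios = c("gland", "vesicles_separate",
                                         "gland_vesicles", "nodes", "postop"))
    truth <- dplyr::rename(coh$truth, original_name = display_name)
    store <- build_feature_store(list.dirs(dir, recursive = FALSE),
                                 labels = truth, resolution = 32L)
    tc <- training_config(n_folds = 2L, epochs = 8L, input_resolution = 32L,
                          hidden_units = 32L, seed = 5L)
    ens <- suppressWarnings(train_ensemble(store, tc))
    cache <<- list(config = cfg, cohort = coh, truth = truth, store = store,
                   ensemble = ens, dir = dir)
    cache
  }
})
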