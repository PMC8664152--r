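test_that("projections are max-projections with the documented view axes", {
  grid <- array(FALSE, c(6, 7, 5))
  expect_true(all(project(grid)$transversal == 0))
  grid[2, 3, 4] <- TRUE
  p <- project(grid)
  expect_equal(sum(p$transversal), 1); expect_equal(p$transversal[2, 3], 1)
  expect_equal(sum(p$coronal), 1);     expect_equal(p$coronal[4, 3], 1)
  expect_equal(sum(p$sagittal), 1);    expect_equal(p$sagittal[4, 2], 1)
})

test_that("projections equal the brute-force ray-sum-truncate oracle on random masks", {
  withr::with_seed(23, {
    for (i in 1:20) {
      grid <- array(stats::runif(16^3) < 0.1, c(16, 16, 16))
      p <- project(grid)
      o <- oracle_project(grid)
      expect_identical(p$transversal, o$transversal)
      expect_identical(p$coronal, o$coronal)
      expect_identical(p$sagittal, o$sagittal)
      expect_true(all(unlist(p) %in% c(0, 1)))
    }
  })
})

test_that("center-of-mass slice is the rounded mean slice index", {
  grid <- array(FALSE, c(4, 4, 12))
  grid[1, 1, 7] <- TRUE
  expect_equal(center_of_mass_slice(grid), 7L)
  grid2 <- array(FALSE, c(4, 4, 12))
  grid2[1:2, 1, 4] <- TRUE; grid2[1:2, 1, 6] <- TRUE
  expect_equal(center_of_mass_slice(grid2), 5L)
  grid3 <- array(FALSE, c(4, 4, 12))
  grid3[1:3, 1, 2] <- TRUE; grid3[1, 1, 10] <- TRUE
  expect_equal(center_of_mass_slice(grid3), 4L)  # mean 4.0
  # ties round half up: equal mass on slices 2 and 3 -> 2.5 -> 3
  grid4 <- array(FALSE, c(4, 4, 12))
  grid4[1, 1, 2] <- TRUE; grid4[1, 1, 3] <- TRUE
  expect_equal(center_of_mass_slice(grid4), 3L)
  expect_error(center_of_mass_slice(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("AddMap weights, truncation and exclusions follow the contract", {
  d <- c(8, 8, 3)
  target <- rtnamer:::new_mask(array(rep(c(FALSE, TRUE, FALSE), each = 64), d))
  full <- rtnamer:::new_mask(array(TRUE, d))
  cfgam <- addmap_config()

  # no other structures -> all-zero AddMap (target never contributes)
  am0 <- compute_addmap(target, list(), cfgam)
  expect_true(all(am0$image == 0))
  expect_equal(am0$slice_index, 2L)

  # body-only pixel = 0.1
  am1 <- compute_addmap(target, list(list(mask = full, is_body = TRUE)), cfgam)
  expect_true(all(am1$image == 0.1))

  # body + 5 others truncates at 1
  others <- c(list(list(mask = full, is_body = TRUE)),
              replicate(5, list(mask = full, is_body = FALSE), simplify = FALSE))
  am6 <- compute_addmap(target, others, cfgam)
  expect_true(all(am6$image == 1))

  # monotone non-decreasing in overlapping structures; range stays in [0, cap]
  prev <- am0$image
  accum <- list()
  for (j in 1:6) {
    accum <- c(accum, list(list(mask = full, is_body = FALSE)))
    cur <- compute_addmap(target, accum, cfgam)$image
    expect_true(all(cur >= prev))
    expect_true(all(cur >= 0 & cur <= cfgam$cap))
    prev <- cur
  }
  expect_error(compute_addmap(rtnamer:::new_mask(array(FALSE, d)), list(), cfgam),
               "empty")
  expect_error(addmap_config(body_weight = 0.5, other_weight = 0.2), "<=")
})

test_that("nearest-neighbour resize follows the pixel-center index mapping", {
  img <- matrix(stats::runif(256 * 256), 256, 256)
  expect_identical(resize_nearest(img, 256L), img)
  checker <- matrix(c(1, 0, 0, 1), 2, 2)
  up <- resize_nearest(checker, 4L)
  expect_equal(up, checker[c(1, 1, 2, 2), c(1, 1, 2, 2)])
  # downsampling against a per-pixel oracle of the stated convention
  withr::with_seed(5, src <- matrix(stats::runif(48 * 48) < 0.5, 48, 48) * 1)
  for (target in c(17L, 32L)) {
    out <- resize_nearest(src, target)
    oracle <- matrix(0, target, target)
    for (i in seq_len(target)) {
      for (j in seq_len(target)) {
        oracle[i, j] <- src[ceiling((i - 0.5) * 48 / target),
                            ceiling((j - 0.5) * 48 / target)]
      }
    }
    expect_equal(out, oracle, ignore_attr = TRUE)
    expect_true(all(out %in% c(0, 1)))
  }
})

test_that("feature store excludes optimization and empty structures and applies corrections", {
  fx <- small_pipeline_fixture()
  sub_dirs <- list.dirs(fx$dir, recursive = FALSE)
  truth_all <- read_cohort_truth(fx$dir)
  # per subject: samples = truth rows minus empty structures
  ss1 <- read_structure_set(sub_dirs[1])
  n_opt <- sum(is_optimization_structure(
    vapply(ss1$structures, `[[`, character(1), "name")))
  n_empty <- sum(vapply(ss1$structures, `[[`, logical(1), "is_empty"))
  stored <- fx$store[fx$store$subject_id == ss1$subject_id, ]
  expect_equal(nrow(stored), length(ss1$structures) - n_opt - n_empty)
  # store keys partition by subject
  expect_equal(sort(unique(fx$store$subject_id)), sort(fx$cohort$subjects))
  expect_false(any(duplicated(fx$store[c("subject_id", "roi_number")])))

  # a correction entry overrides the name-derived label
  corr <- tibble::tibble(subject_id = stored$subject_id[1],
                         original_name = stored$original_name[1],
                         corrected_class_id = 11L)
  store2 <- build_feature_store(sub_dirs[1], labels = fx$truth,
                                corrections = corr, resolution = 32L)
  expect_equal(store2$class_id[1], 11L)
  expect_equal(store2$class_id[-1], stored$class_id[-1])

  # unresolvable training label errors with the offending name
  bad_truth <- fx$truth[fx$truth$original_name != stored$original_name[1], ]
  expect_error(build_feature_store(sub_dirs[1], labels = bad_truth,
                                   resolution = 32L),
               stored$original_name[1], fixed = TRUE)
})

test_that("CTV and PTV samples see each other's footprint in the AddMap", {
  cfg <- phantom_config(seed = 21L, optimization_injection_rate = 0,
                        empty_structure_rate = 0)
  sub <- generate_subject(cfg, 2101L, scenario = "gland")
  cn <- vapply(sub$structures, `[[`, character(1), "canonical_name")
  masks <- subject_masks(sub)
  i_ctv <- which(cn == "GlandCTV")[1]; i_ptv <- which(cn == "GlandPTV")[1]
  others_of <- function(i) lapply(setdiff(seq_along(masks), i), function(j) {
    list(mask = masks[[j]], is_body = cn[j] == "Body")
  })
  am_ctv <- compute_addmap(masks[[i_ctv]], others_of(i_ctv))
  # at the CTV's center slice, the PTV footprint is present in the AddMap
  ptv_slice <- masks[[i_ptv]]$grid[, , am_ctv$slice_index]
  expect_true(all(am_ctv$image[ptv_slice] > 0))
  am_ptv <- compute_addmap(masks[[i_ptv]], others_of(i_ptv))
  ctv_slice <- masks[[i_ctv]]$grid[, , am_ptv$slice_index]
  expect_true(all(am_ptv$image[ctv_slice] > 0))
})
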