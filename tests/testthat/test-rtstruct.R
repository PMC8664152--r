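test_that("a 10x10 mm square on a 1 mm grid fills 100 voxels on its slice", {
  geom <- tiny_geometry()
  mask <- rasterize(as_struct(square_contour(0, 0, 10, 3.5)), geom)
  expect_equal(mask$foreground_count, 100L)
  expect_equal(sum(mask$grid[, , 4]), 100)  # z = 3.5 is slice 4
  expect_equal(sum(mask$grid[, , -4]), 0)
  expect_equal(structure_volume(mask, geom), 0.1)
})

test_that("concentric squares produce a ring under the even-odd rule", {
  geom <- tiny_geometry()
  s <- as_struct(square_contour(0, 0, 12, 0.5), square_contour(3, 3, 6, 0.5))
  mask <- rasterize(s, geom)
  expect_equal(mask$foreground_count, 144L - 36L)
  # union fill keeps the inner square filled
  mask_u <- rasterize(s, geom, fill_rule = "union")
  expect_equal(mask_u$foreground_count, 144L)
})

test_that("rasterization is invariant to contour orientation and skips degenerate polygons", {
  geom <- tiny_geometry()
  poly <- square_contour(1, 2, 7, 2.5)
  m1 <- rasterize(as_struct(poly), geom)
  m2 <- rasterize(as_struct(poly[rev(seq_len(nrow(poly))), ]), geom)
  expect_identical(m1$grid, m2$grid)
  expect_warning(m3 <- rasterize(as_struct(poly[1:2, , drop = FALSE]), geom),
                 "degenerate")
  expect_equal(m3$foreground_count, 0L)
  expect_equal(rasterize(list(contours = list()), geom)$foreground_count, 0L)
})

test_that("volume is foreground count times voxel volume", {
  geom <- image_geometry(c(0, 0, 0), c(2, 2, 2.5), c(10L, 10L, 4L))
  grid <- array(FALSE, c(10, 10, 4))
  grid[1:10, 1:10, 1] <- TRUE  # 100 voxels
  mask <- rtnamer:::new_mask(grid)
  expect_equal(structure_volume(mask, geom), 1.0)
  expect_equal(structure_volume(rtnamer:::new_mask(array(FALSE, c(10, 10, 4))),
                                geom), 0.0)
})

test_that("rasterization matches a point-in-polygon oracle on random convex polygons", {
  geom <- image_geometry(c(0.5, 0.5, 0.5), c(1, 1, 1), c(24L, 24L, 2L))
  withr::with_seed(17, {
    for (i in 1:12) {
      poly <- random_convex_polygon(12L, cx = stats::runif(1, 6, 18),
                                    cy = stats::runif(1, 6, 18),
                                    r = stats::runif(1, 2, 6))
      mask <- rasterize(as_struct(cbind(poly, 0.5)), geom)
      expect_equal(mask$foreground_count,
                   oracle_fill_count(list(poly), geom))
    }
  })
})

test_that("subject directories round-trip: names byte-exact, contours preserved", {
  cfg <- phantom_config(dims = c(32L, 32L, 8L), spacing = c(12, 12, 24),
                        seed = 8L, empty_structure_rate = 1)
  sub <- generate_subject(cfg, 88L)
  dir <- withr::local_tempdir()
  withr::with_seed(9, write_subject(sub, dir))
  ss <- read_structure_set(dir)
  expect_equal(vapply(ss$structures, `[[`, character(1), "name"),
               vapply(sub$structures, `[[`, character(1), "name"))
  expect_equal(ss$subject_id, sub$subject_id)
  expect_equal(ss$geometry$dims, sub$geometry$dims)
  expect_equal(ss$geometry$spacing, sub$geometry$spacing)
  # injected empty structure is parsed and flagged, not dropped
  empties <- vapply(ss$structures, `[[`, logical(1), "is_empty")
  expect_equal(which(empties),
               which(vapply(sub$structures, `[[`, logical(1), "is_empty")))
})

test_that("read_structure_set rejects ambiguous or incomplete directories", {
  cfg <- phantom_config(dims = c(32L, 32L, 8L), spacing = c(12, 12, 24), seed = 8L)
  sub <- generate_subject(cfg, 77L)
  dir <- withr::local_tempdir()
  withr::with_seed(9, write_subject(sub, dir))
  # duplicate structure set -> ambiguous
  file.copy(file.path(dir, "rtstruct.dcm"), file.path(dir, "rtstruct2.dcm"))
  expect_error(read_structure_set(dir), "exactly one RT Structure Set")
  file.remove(file.path(dir, "rtstruct2.dcm"))
  # no image series -> geometry error
  dir2 <- withr::local_tempdir()
  file.copy(file.path(dir, "rtstruct.dcm"), file.path(dir2, "rtstruct.dcm"))
  expect_error(read_structure_set(dir2), "no image series")
})

test_that("write_renamed_copy edits only the requested names and keeps contours byte-identical", {
  cfg <- phantom_config(dims = c(32L, 32L, 8L), spacing = c(12, 12, 24), seed = 8L)
  sub <- generate_subject(cfg, 55L)
  dir <- withr::local_tempdir()
  withr::with_seed(9, write_subject(sub, dir))
  ss <- read_structure_set(dir)

  # identity plan: contour payloads byte-identical to the source
  out1 <- withr::local_tempfile(fileext = ".dcm")
  plan_id <- stats::setNames(
    vapply(ss$structures, `[[`, character(1), "name"),
    vapply(ss$structures, `[[`, integer(1), "roi_number"))
  write_renamed_copy(ss, plan_id, out1)
  dir_cp <- withr::local_tempdir()
  for (f in list.files(dir, "img", full.names = TRUE)) file.copy(f, dir_cp)
  file.copy(out1, file.path(dir_cp, "rtstruct.dcm"))
  back <- read_structure_set(dir_cp)
  expect_identical(contour_payloads(back), contour_payloads(ss))
  expect_equal(vapply(back$structures, `[[`, character(1), "name"),
               unname(plan_id))
  # fresh SOP instance UID
  expect_false(identical(
    rtnamer:::dcm_string(rtnamer:::dcm_find(back$dicom$dataset, 0x0008L, 0x0018L)),
    rtnamer:::dcm_string(rtnamer:::dcm_find(ss$dicom$dataset, 0x0008L, 0x0018L))))

  # single rename: only ROI 3 changes
  out2 <- withr::local_tempfile(fileext = ".dcm")
  write_renamed_copy(ss, c("3" = "GlandPTV 78Gy"), out2)
  file.copy(out2, file.path(dir_cp, "rtstruct.dcm"), overwrite = TRUE)
  back2 <- read_structure_set(dir_cp)
  names_before <- vapply(ss$structures, `[[`, character(1), "name")
  names_after <- vapply(back2$structures, `[[`, character(1), "name")
  expect_equal(names_after[3], "GlandPTV 78Gy")
  expect_equal(names_after[-3], names_before[-3])
  expect_identical(contour_payloads(back2), contour_payloads(ss))

  expect_error(write_renamed_copy(ss, c("999" = "Nope"), tempfile()), "unknown ROI")
  expect_error(write_renamed_copy(ss, c("1" = strrep("a", 65)), tempfile()),
               "LO length")
  expect_error(write_renamed_copy(ss, c("1" = ""), tempfile()), "non-empty")
})
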