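test_that("subjects regenerate bit-identically from the same seed", {
  cfg <- phantom_config(seed = 2L)
  s1 <- generate_subject(cfg, 1234L)
  s2 <- generate_subject(cfg, 1234L)
  expect_identical(s1, s2)
  s3 <- generate_subject(cfg, 1235L)
  expect_false(identical(s1$structures, s3$structures))
})

test_that("every PTV strictly contains its CTV and targets sit inside the body", {
  cfg <- phantom_config(seed = 6L, optimization_injection_rate = 0,
                        empty_structure_rate = 0)
  seen <- character(0)
  for (seed in 601:608) {
    sub <- generate_subject(cfg, seed)
    cn <- vapply(sub$structures, `[[`, character(1), "canonical_name")
    seen <- union(seen, cn)
    masks <- subject_masks(sub)
    body <- masks[[which(cn == "Body")]]$grid
    for (i in which(endsWith(cn, "CTV"))) {
      j <- which(cn == sub("CTV$", "PTV", cn[i]))
      expect_length(j, 1L)
      ctv <- masks[[i]]$grid; ptv <- masks[[j]]$grid
      expect_true(all(ptv[ctv]))
      expect_gt(sum(ptv), sum(ctv))
    }
    if ("GTV" %in% cn) {
      gtv <- masks[[which(cn == "GTV")]]$grid
      ctv_host <- masks[[which(cn %in% c("GlandCTV", "GlandVesiclesCTV"))[1]]]$grid
      expect_true(all(ctv_host[gtv]))
    }
    for (i in seq_along(masks)) {
      if (cn[i] %in% c("Body", "CouchSurface", "CouchInterior")) next
      expect_true(all(body[masks[[i]]$grid]))
    }
  }
  # the scenario mix exercises all five target families across a few subjects
  expect_true(length(intersect(seen, c("GlandCTV", "GlandVesiclesCTV",
                                       "VesicleCTV", "LymphNodesCTV",
                                       "ProstateBedCTV"))) >= 3)
})

test_that("the PTV margin is about 7 mm along the axes (distance oracle)", {
  cfg <- phantom_config(seed = 9L)
  found <- FALSE
  for (seed in 901:906) {
    sub <- generate_subject(cfg, seed)
    cn <- vapply(sub$structures, `[[`, character(1), "canonical_name")
    if (!"GlandCTV" %in% cn) next
    found <- TRUE
    masks <- subject_masks(sub)
    ctv <- masks[[which(cn == "GlandCTV")[1]]]$grid
    ptv <- masks[[which(cn == "GlandPTV")[1]]]$grid
    com <- round(colMeans(which(ctv, arr.ind = TRUE)))
    sp <- sub$geometry$spacing
    # along each axis through the CTV center of mass, the PTV border extends
    # ~7 mm beyond the CTV border (within one voxel)
    for (axis in 1:3) {
      line_of <- function(g) {
        idx <- switch(axis,
                      g[, com[2], com[3]], g[com[1], , com[3]], g[com[1], com[2], ])
        range(which(idx))
      }
      rc <- line_of(ctv); rp <- line_of(ptv)
      step <- sp[c(2, 1, 3)][axis]
      expect_lte(abs((rc[1] - rp[1]) * step - cfg$ptv_margin_mm), step)
      expect_lte(abs((rp[2] - rc[2]) * step - cfg$ptv_margin_mm), step)
    }
    break
  }
  expect_true(found)
})

test_that("scrambled names stay class-consistent and never collide with optimization prefixes", {
  withr::with_seed(44, {
    draws <- replicate(20, scramble_name("FemoralHead_R")$name)
    expect_true(all(draws %in% c("FemoralHead_R", "caput dx", "caput dx1",
                                 "avoid dx", "Femur_R")))
    ptv <- scramble_name("GlandPTV", dose = "78")
    expect_equal(ptv$dose_token, "78Gy")
    expect_equal(extract_dose_token(ptv$name), "78Gy")
  })
  expect_equal(scramble_name("Bladder", scramble = FALSE)$name, "Bladder")
  expect_error(scramble_name("NotAClass"), "unknown class")
  # no synonym pool entry can be mistaken for an optimization structure
  withr::with_seed(45, {
    for (cls in trainable_classes(default_taxonomy())$canonical_name) {
      for (k in 1:10) {
        nm <- scramble_name(cls, dose = "42.7")$name
        expect_false(is_optimization_structure(nm))
      }
    }
  })
})

test_that("cohorts are reproducible and the truth table lists exactly the non-optimization structures", {
  cfg <- phantom_config(dims = c(32L, 32L, 8L), spacing = c(12, 12, 24),
                        seed = 13L, optimization_injection_rate = 0.3,
                        empty_structure_rate = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_cohort(5, cfg, out_dir = d1)
  c2 <- generate_cohort(5, cfg, out_dir = d2)
  expect_identical(c1$truth, c2$truth)
  expect_identical(readLines(file.path(d1, "ground_truth.csv")),
                   readLines(file.path(d2, "ground_truth.csv")))

  n_expected <- 0L
  for (i in 1:5) {
    sub <- generate_subject(cfg, cfg$seed * 10000L + i)
    n_expected <- n_expected +
      sum(!vapply(sub$structures, `[[`, logical(1), "is_optimization"))
  }
  expect_equal(nrow(c1$truth), n_expected)

  # reading back a subject reproduces the generator masks voxel-for-voxel
  sub1 <- generate_subject(cfg, cfg$seed * 10000L + 1L, subject_id = "sub0001")
  ss <- read_structure_set(file.path(d1, "sub0001"))
  masks <- subject_masks(sub1)
  for (s in ss$structures) {
    expect_identical(rasterize(s, ss$geometry)$grid,
                     masks[[as.character(s$roi_number)]]$grid)
  }
})

test_that("anomaly injection produces fused targets and volume outliers on demand", {
  cfg <- phantom_config(seed = 19L, fused_target_rate = 1,
                        volume_outlier_rate = 1,
                        optimization_injection_rate = 0)
  sub <- generate_subject(cfg, 1901L)
  cn <- vapply(sub$structures, `[[`, character(1), "canonical_name")
  anom <- vapply(sub$structures, `[[`, logical(1), "is_anomalous")
  expect_true("Other" %in% cn)
  expect_true(anom[which(cn == "Other")])
  expect_true(anom[which(cn == "Bladder")])
  # the outlier bladder is far larger than a regular one
  cfg0 <- phantom_config(seed = 19L)
  sub0 <- generate_subject(cfg0, 1901L)
  m1 <- rasterize(sub$structures[[which(cn == "Bladder")]], sub$geometry)
  cn0 <- vapply(sub0$structures, `[[`, character(1), "canonical_name")
  m0 <- rasterize(sub0$structures[[which(cn0 == "Bladder")]], sub0$geometry)
  expect_gt(structure_volume(m1, sub$geometry),
            3 * structure_volume(m0, sub0$geometry))
})
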