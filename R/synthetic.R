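# Synthetic pelvic phantom cohorts: parametric organ/target/support shapes
# with the geometric relations the classifier must learn (PTV = CTV plus an
# isotropic margin, U-shaped elective node targets, couch slabs, body
# outline), clinically messy display names, injected optimization structures.
# Shapes are generated as per-slice polygons in patient coordinates (mm), so
# the written RTSTRUCT contours, re-rasterized, reproduce the generator's
# masks exactly.

#' Phantom cohort configuration
#'
#' @param dims Grid (rows, columns, slices); default 128 x 128 x 64.
#' @param spacing Voxel spacing mm; default 3 x 3 x 3.
#' @param ptv_margin_mm Isotropic CTV-to-PTV margin (default 7 mm).
#' @param name_scrambling Draw clinical-style display names (default TRUE);
#'   when FALSE structures keep their canonical names.
#' @param optimization_injection_rate Expected number of injected
#'   optimization structures per anatomical structure (default 0.2).
#' @param empty_structure_rate Probability of adding one empty (contour-less)
#'   structure per subject (default 0.1).
#' @param fused_target_rate Probability of adding one out-of-taxonomy fused
#'   target (gland + vesicles + nodes in a single structure, ground truth
#'   `"Other"`); default 0.
#' @param volume_outlier_rate Probability of scaling one organ far outside
#'   its class volume range (flagged in the truth table); default 0.
#' @param double_ctv_rate Probability of adding a second gland CTV with a
#'   1 mm extra margin (CTV/PTV-confusion stress case); default 0.
#' @param seed Integer cohort seed.
#' @return An `rtn_phantom_config` list.
#' @export
phantom_config <- function(dims = c(128L, 128L, 64L), spacing = c(3, 3, 3),
                           ptv_margin_mm = 7, name_scrambling = TRUE,
                           optimization_injection_rate = 0.2,
                           empty_structure_rate = 0.1,
                           fused_target_rate = 0,
                           volume_outlier_rate = 0,
                           double_ctv_rate = 0,
                           seed = 1L) {
  if (ptv_margin_mm <= 0) stop("ptv_margin_mm must be positive", call. = FALSE)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 ptv_margin_mm = ptv_margin_mm,
                 name_scrambling = isTRUE(name_scrambling),
                 optimization_injection_rate = optimization_injection_rate,
                 empty_structure_rate = empty_structure_rate,
                 fused_target_rate = fused_target_rate,
                 volume_outlier_rate = volume_outlier_rate,
                 double_ctv_rate = double_ctv_rate,
                 seed = as.integer(seed)),
            class = "rtn_phantom_config")
}

phantom_geometry <- function(config) {
  # dims are (rows, columns, slices); spacing is (x = column, y = row, z)
  extent <- c(config$dims[2] * config$spacing[1],
              config$dims[1] * config$spacing[2],
              config$dims[3] * config$spacing[3])
  image_geometry(origin = -extent / 2 + config$spacing / 2,
                 spacing = config$spacing, dims = config$dims)
}

# ---- shape primitives (per-slice polygons) --------------------------------

ellipse_poly <- function(cx, cy, rx, ry, z, n = 40L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + rx * cos(th), cy + ry * sin(th), z)
}

ellipsoid_contours <- function(center, radii, slice_z, n = 40L) {
  out <- list()
  for (z in slice_z) {
    u <- (z - center[3]) / radii[3]
    if (abs(u) >= 1) next
    s <- sqrt(1 - u^2)
    if (radii[1] * s < 0.5) next
    out[[length(out) + 1L]] <- ellipse_poly(center[1], center[2],
                                            radii[1] * s, radii[2] * s, z, n)
  }
  out
}

box_contours <- function(xlim, ylim, zlim, slice_z) {
  out <- list()
  for (z in slice_z) {
    if (z < zlim[1] || z > zlim[2]) next
    out[[length(out) + 1L]] <- cbind(
      c(xlim[1], xlim[2], xlim[2], xlim[1]),
      c(ylim[1], ylim[1], ylim[2], ylim[2]), z)
  }
  out
}

tube_contours <- function(cx, cy, r, zlim, slice_z, wobble = 0, n = 28L) {
  out <- list()
  for (z in slice_z) {
    if (z < zlim[1] || z > zlim[2]) next
    out[[length(out) + 1L]] <- ellipse_poly(cx + wobble * sin(z / 25), cy, r, r, z, n)
  }
  out
}

# U-shaped band: annular sector from th1 to th2 (radians, gap anterior),
# outer arc out and inner arc back.
ushape_contours <- function(cx, cy, r_out, r_in, th1, th2, zlim, slice_z,
                            n = 36L) {
  th_o <- seq(th1, th2, length.out = n)
  th_i <- rev(th_o)
  poly_xy <- cbind(c(cx + r_out * cos(th_o), cx + r_in * cos(th_i)),
                   c(cy + r_out * sin(th_o), cy + r_in * sin(th_i)))
  out <- list()
  for (z in slice_z) {
    if (z < zlim[1] || z > zlim[2]) next
    out[[length(out) + 1L]] <- cbind(poly_xy, z)
  }
  out
}

# ---- display-name scrambling ----------------------------------------------

.name_pools <- list(
  Body           = c("BODY", "Body", "External", "outline", "kontur"),
  Bladder        = c("Bladder", "blasa", "Urinary Bladder", "bladder1"),
  Rectum         = c("Rectum", "rektum", "Rectum1", "rect"),
  FemoralHead_L  = c("FemoralHead_L", "caput sin", "caput sin1", "avoid sin", "Femur_L"),
  FemoralHead_R  = c("FemoralHead_R", "caput dx", "caput dx1", "avoid dx", "Femur_R"),
  PenileBulb     = c("PenileBulb", "bulbus", "penile bulb", "Bulb"),
  BowelBag       = c("BowelBag", "bowel", "tarm", "Bowel_Bag"),
  Genitalia      = c("Genitalia", "genitalia", "Genitals"),
  AnalCanal      = c("AnalCanal", "anal canal", "analkanal", "Anus"),
  CouchSurface   = c("CouchSurface", "Couch Surface", "bordsyta"),
  CouchInterior  = c("CouchInterior", "Couch Interior", "bordsinre"),
  GTV            = c("GTV %s", "GTV-T %s", "gtv %s"),
  GlandCTV       = c("CTV %s", "CTV prost %s", "ctv1 %s", "CTVp %s"),
  GlandPTV       = c("PTV %s", "PTV prost %s", "ptv1 %s", "PTVp %s"),
  GlandVesiclesCTV = c("CTV prost+ves %s", "CTVpv %s", "ctv prostata sv %s"),
  GlandVesiclesPTV = c("PTV prost+ves %s", "PTVpv %s", "ptv prostata sv %s"),
  VesicleCTV     = c("CTV ves %s", "CTVsv %s", "ctv vesiklar %s"),
  VesiclePTV     = c("PTV ves %s", "PTVsv %s", "ptv vesiklar %s"),
  LymphNodesCTV  = c("CTV lgll %s", "CTVn %s", "ctv lymph %s"),
  LymphNodesPTV  = c("PTV lgll %s", "PTVn %s", "ptv lymph %s"),
  ProstateBedCTV = c("CTV bed %s", "CTVsb %s", "ctv prostate bed %s"),
  ProstateBedPTV = c("PTV bed %s", "PTVsb %s", "ptv prostate bed %s"),
  Other          = c("CTV prost+ves+lgll %s", "CTV total %s")
)

.opt_name_pool <- c("Tuning_rect", "Tuning bladder", "Help post", "HelpRing",
                    "Xbase", "zRing1", "Dose shell", "Match iso", "match ant")

#' Draw a clinical-style display name for a canonical class
#'
#' Samples from a per-class synonym pool (misspellings, language variants,
#' numeric suffixes) using the current RNG state; target classes embed a dose
#' token in one of several unit spellings. With `scramble = FALSE` the
#' canonical name is returned unchanged.
#'
#' @param canonical_name Canonical class name present in the pools.
#' @param dose Optional dose amount string (e.g. `"78"` or `"42.7"`); its
#'   normalized token is `paste0(dose, "Gy")`.
#' @param scramble Draw from the pool (default) or return canonical.
#' @return List `name` (display name) and `dose_token` (normalized, or NA).
#' @export
scramble_name <- function(canonical_name, dose = NULL, scramble = TRUE) {
  pool <- .name_pools[[canonical_name]]
  if (is.null(pool)) stop("unknown class: ", canonical_name, call. = FALSE)
  if (!scramble) {
    return(list(name = canonical_name, dose_token = NA_character_))
  }
  template <- sample(pool, 1L)
  if (grepl("%s", template, fixed = TRUE)) {
    if (is.null(dose)) dose <- "78"
    unit <- sample(c("Gy", " Gy", "gy", " gy"), 1L)
    shown <- if (stats::runif(1) < 0.2) sub(".", ",", dose, fixed = TRUE) else dose
    name <- sprintf(template, paste0(shown, unit))
    token <- paste0(dose, "Gy")
  } else {
    name <- template
    token <- NA_character_
  }
  list(name = name, dose_token = token)
}

# ---- subject generation ---------------------------------------------------

jit <- function(x, frac = 0.08) x * stats::runif(length(x), 1 - frac, 1 + frac)

#' Generate one synthetic phantom subject
#'
#' Builds the per-structure contour stacks for one subject: elliptical
#' cylinder body, two couch slabs, organs at risk at anatomically plausible
#' offsets, and targets selected by a scenario (gland-only, gland + separate
#' vesicles, fused gland+vesicles, pelvic nodes, post-operative prostate
#' bed); every PTV is its CTV expanded isotropically by the configured
#' margin. All randomness derives from `subject_seed`, so regeneration is
#' bit-identical.
#'
#' @param config An [phantom_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Display id (default derived from the seed).
#' @param scenario Optional fixed scenario (one of `"gland"`,
#'   `"vesicles_separate"`, `"gland_vesicles"`, `"nodes"`, `"postop"`);
#'   drawn from the default case mix when `NULL`.
#' @return An `rtn_phantom_subject`: list with `subject_id`, `geometry`,
#'   `scenario` and `structures` (each: `roi_number`, `name`,
#'   `canonical_name`, `dose_token`, `contours`, `is_optimization`,
#'   `is_empty`, `is_anomalous`).
#' @export
generate_subject <- function(config, subject_seed,
                             subject_id = sprintf("sub%06d", subject_seed),
                             scenario = NULL) {
  stopifnot(inherits(config, "rtn_phantom_config"))
  geometry <- phantom_geometry(config)
  zs <- geometry$slice_z
  m <- config$ptv_margin_mm
  all_scenarios <- c("gland", "vesicles_separate", "gland_vesicles",
                     "nodes", "postop")
  if (!is.null(scenario)) scenario <- match.arg(scenario, all_scenarios)
  withr::with_seed(as.integer(subject_seed), {
    if (is.null(scenario)) {
      scenario <- sample(all_scenarios, 1L, prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
    }
    size <- stats::runif(1, 0.92, 1.08)  # global subject size factor

    anat <- list()
    add <- function(canonical, contours, anomalous = FALSE, dose = NULL) {
      anat[[length(anat) + 1L]] <<- list(canonical_name = canonical,
                                         contours = contours,
                                         is_anomalous = anomalous,
                                         dose = dose)
    }

    body_r <- jit(c(165, 105), 0.05) * size
    body_c <- c(stats::runif(1, -3, 3), stats::runif(1, 0, 8))
    add("Body", box_like_cylinder(body_c, body_r, zs))
    add("CouchSurface",
        box_contours(c(-152, 152), body_c[2] + body_r[2] + c(2, 8), range(zs), zs))
    add("CouchInterior",
        box_contours(c(-152, 152), body_c[2] + body_r[2] + c(8, 38), range(zs), zs))

    outlier <- stats::runif(1) < config$volume_outlier_rate
    bl_scale <- if (outlier) 1.9 else 1
    add("Bladder",
        ellipsoid_contours(c(stats::runif(1, -4, 4), -35 + stats::runif(1, -5, 5),
                             20 + stats::runif(1, -6, 6)),
                           jit(c(40, 33, 33)) * size * bl_scale, zs),
        anomalous = outlier)
    add("Rectum",
        tube_contours(stats::runif(1, -4, 4), 45 + stats::runif(1, -4, 4),
                      jit(14) * size, c(-62, 40) + stats::runif(1, -5, 5), zs,
                      wobble = stats::runif(1, 0, 6)))
    add("FemoralHead_L", ellipsoid_contours(c(95 + stats::runif(1, -5, 5),
                                              10 + stats::runif(1, -5, 5),
                                              -5 + stats::runif(1, -5, 5)),
                                            jit(c(24, 24, 24)) * size, zs))
    add("FemoralHead_R", ellipsoid_contours(c(-95 + stats::runif(1, -5, 5),
                                              10 + stats::runif(1, -5, 5),
                                              -5 + stats::runif(1, -5, 5)),
                                            jit(c(24, 24, 24)) * size, zs))
    add("PenileBulb", ellipsoid_contours(c(stats::runif(1, -3, 3), 18,
                                           -55 + stats::runif(1, -4, 4)),
                                         jit(c(12, 10, 10)) * size, zs))
    add("BowelBag", ellipsoid_contours(c(stats::runif(1, -5, 5), -10, 55),
                                       jit(c(78, 58, 28)) * size, zs))
    add("Genitalia", ellipsoid_contours(c(stats::runif(1, -3, 3), -70,
                                          -68 + stats::runif(1, -4, 4)),
                                        jit(c(22, 18, 20)) * size, zs))
    add("AnalCanal", tube_contours(stats::runif(1, -3, 3), 45, jit(8) * size,
                                   c(-78, -56), zs))

    # targets
    gland_c <- c(stats::runif(1, -3, 3), 10 + stats::runif(1, -4, 4),
                 -10 + stats::runif(1, -5, 5))
    gland_r <- jit(c(24, 22, 20)) * size
    lobe_r <- jit(c(10, 8, 10)) * size
    lobe_z <- gland_c[3] + 25
    lobes <- function(extra = 0) c(
      ellipsoid_contours(c(28, 50, lobe_z), lobe_r + extra, zs),
      ellipsoid_contours(c(-28, 50, lobe_z), lobe_r + extra, zs))
    gtv <- function() ellipsoid_contours(gland_c + c(2, -2, 0), gland_r * 0.45, zs)
    uband <- function(extra = 0) {
      ushape_contours(0, 5, 80 + extra, 55 - extra,
                      -0.45 - extra / 80, pi + 0.45 + extra / 80,
                      gland_c[3] + c(-8 - extra, 52 + extra), zs)
    }
    dose_gland <- sample(c("78", "70", "77.5"), 1L)
    dose_ves <- sample(c("50", "42.7"), 1L)
    dose_nodes <- sample(c("42.7", "50"), 1L)
    dose_bed <- "70"
    if (scenario == "gland") {
      add("GTV", gtv(), dose = dose_gland)
      add("GlandCTV", ellipsoid_contours(gland_c, gland_r, zs), dose = dose_gland)
      add("GlandPTV", ellipsoid_contours(gland_c, gland_r + m, zs), dose = dose_gland)
    } else if (scenario == "vesicles_separate") {
      add("GTV", gtv(), dose = dose_gland)
      add("GlandCTV", ellipsoid_contours(gland_c, gland_r, zs), dose = dose_gland)
      add("GlandPTV", ellipsoid_contours(gland_c, gland_r + m, zs), dose = dose_gland)
      add("VesicleCTV", lobes(), dose = dose_ves)
      add("VesiclePTV", lobes(m), dose = dose_ves)
    } else if (scenario == "gland_vesicles") {
      add("GTV", gtv(), dose = dose_gland)
      add("GlandVesiclesCTV",
          c(ellipsoid_contours(gland_c, gland_r, zs), lobes()), dose = dose_gland)
      add("GlandVesiclesPTV",
          c(ellipsoid_contours(gland_c, gland_r + m, zs), lobes(m)),
          dose = dose_gland)
    } else if (scenario == "nodes") {
      add("GTV", gtv(), dose = dose_gland)
      add("GlandCTV", ellipsoid_contours(gland_c, gland_r, zs), dose = dose_gland)
      add("GlandPTV", ellipsoid_contours(gland_c, gland_r + m, zs), dose = dose_gland)
      add("LymphNodesCTV", uband(), dose = dose_nodes)
      add("LymphNodesPTV", uband(m), dose = dose_nodes)
    } else {  # postop prostate bed
      bed_r <- jit(c(26, 22, 19)) * size
      bed_c <- gland_c + c(0, 2, -2)
      add("ProstateBedCTV", ellipsoid_contours(bed_c, bed_r, zs), dose = dose_bed)
      add("ProstateBedPTV", ellipsoid_contours(bed_c, bed_r + m, zs), dose = dose_bed)
    }
    if (stats::runif(1) < config$double_ctv_rate) {
      add("GlandCTV", ellipsoid_contours(gland_c, gland_r + 1, zs),
          dose = dose_gland)
    }
    if (stats::runif(1) < config$fused_target_rate) {
      # fused gland + vesicles + nodes in ONE structure; the node band's
      # inner radius is pushed out so the three parts stay disjoint (a
      # shared-slice overlap would punch even-odd holes)
      fused_band <- ushape_contours(0, 5, 87, 74, -0.45 - m / 80,
                                    pi + 0.45 + m / 80,
                                    gland_c[3] + c(-15, 59), zs)
      add("Other",
          c(ellipsoid_contours(gland_c, gland_r + m, zs), lobes(m), fused_band),
          anomalous = TRUE, dose = dose_gland)
    }

    structures <- lapply(anat, function(a) {
      sn <- scramble_name(a$canonical_name, dose = a$dose,
                          scramble = config$name_scrambling)
      list(name = sn$name, canonical_name = a$canonical_name,
           dose_token = sn$dose_token, contours = a$contours,
           is_optimization = FALSE, is_empty = FALSE,
           is_anomalous = a$is_anomalous)
    })

    n_opt <- stats::rbinom(1L, length(anat), config$optimization_injection_rate)
    for (i in seq_len(n_opt)) {
      ctr <- c(stats::runif(1, -60, 60), stats::runif(1, -40, 60),
               stats::runif(1, -50, 50))
      structures[[length(structures) + 1L]] <- list(
        name = paste0(sample(.opt_name_pool, 1L), sample(1:9, 1L)),
        canonical_name = NA_character_, dose_token = NA_character_,
        contours = ellipsoid_contours(ctr, jit(c(15, 15, 12)), zs),
        is_optimization = TRUE, is_empty = FALSE, is_anomalous = FALSE)
    }
    if (stats::runif(1) < config$empty_structure_rate) {
      structures[[length(structures) + 1L]] <- list(
        name = paste0("spare", sample(1:9, 1L)), canonical_name = "Other",
        dose_token = NA_character_, contours = list(),
        is_optimization = FALSE, is_empty = TRUE, is_anomalous = FALSE)
    }
    for (i in seq_along(structures)) structures[[i]]$roi_number <- i

    structure(list(subject_id = subject_id, geometry = geometry,
                   scenario = scenario, structures = structures),
              class = "rtn_phantom_subject")
  })
}

# elliptical cylinder (constant cross-section over all slices)
box_like_cylinder <- function(center, radii, slice_z) {
  lapply(slice_z, function(z) ellipse_poly(center[1], center[2],
                                           radii[1], radii[2], z, 48L))
}

#' Rasterize a phantom subject's structures to ground-truth masks
#'
#' @param subject An `rtn_phantom_subject`.
#' @return Named list (by ROI number) of `rtn_mask` objects.
#' @export
subject_masks <- function(subject) {
  stopifnot(inherits(subject, "rtn_phantom_subject"))
  masks <- lapply(subject$structures, rasterize, geometry = subject$geometry)
  names(masks) <- vapply(subject$structures, `[[`, integer(1), "roi_number")
  masks
}

#' Write a phantom subject as a DICOM subject directory
#'
#' Writes a uniform-intensity CT-like image series (geometry carrier only)
#' plus the RTSTRUCT file.
#'
#' @param subject An `rtn_phantom_subject`.
#' @param dir Output directory (created).
#' @param modality `"CT"` or `"MR"`.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir, modality = "CT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study_uid <- random_uid(); series_uid <- random_uid(); frame_uid <- random_uid()
  geometry <- subject$geometry
  for (k in seq_len(geometry$dims[3])) {
    write_image_slice(file.path(dir, sprintf("img_%03d.dcm", k)), geometry, k,
                      modality, subject$subject_id, study_uid, series_uid,
                      frame_uid)
  }
  write_structure_file(file.path(dir, "rtstruct.dcm"), subject$structures,
                       subject$subject_id, study_uid, frame_uid)
  invisible(dir)
}

#' Generate a synthetic phantom cohort on disk
#'
#' Writes one DICOM subject directory per subject plus a ground-truth CSV
#' (`ground_truth.csv`: subject_id, roi_number, display_name, true_class,
#' class_id, dose_token, is_anomalous — optimization structures are not
#' listed) and a generation manifest (`manifest.json`).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config An [phantom_config()].
#' @param out_dir Output cohort directory.
#' @param modality Image series modality (`"CT"` or `"MR"`).
#' @param scenarios Optional vector of scenario labels, recycled over
#'   subjects (e.g. to guarantee class coverage in a small cohort); the
#'   default draws each subject's scenario from the case mix.
#' @return List with `dir`, `truth` (tibble) and `subjects` (ids), invisibly.
#' @export
generate_cohort <- function(n_subjects, config = phantom_config(),
                            out_dir = tempfile("cohort"), modality = "CT",
                            scenarios = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(scenarios)) scenarios <- rep_len(scenarios, n_subjects)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tax <- default_taxonomy()
  truth_rows <- list()
  scenarios_used <- character(n_subjects)
  ids <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    subject_seed <- config$seed * 10000L + i
    subject <- generate_subject(config, subject_seed,
                                subject_id = sprintf("sub%04d", i),
                                scenario = scenarios[i])
    ids[i] <- subject$subject_id
    scenarios_used[i] <- subject$scenario
    withr::with_seed(subject_seed + 5000L,
                     write_subject(subject, file.path(out_dir, subject$subject_id),
                                   modality = modality))
    keep <- !vapply(subject$structures, `[[`, logical(1), "is_optimization")
    truth_rows[[i]] <- tibble::tibble(
      subject_id = subject$subject_id,
      roi_number = vapply(subject$structures[keep], `[[`, integer(1), "roi_number"),
      display_name = vapply(subject$structures[keep], `[[`, character(1), "name"),
      true_class = vapply(subject$structures[keep], `[[`, character(1),
                          "canonical_name"),
      class_id = tax$classes$class_id[match(
        vapply(subject$structures[keep], `[[`, character(1), "canonical_name"),
        tax$classes$canonical_name)],
      dose_token = vapply(subject$structures[keep], `[[`, character(1),
                          "dose_token"),
      is_anomalous = vapply(subject$structures[keep], `[[`, logical(1),
                            "is_anomalous"))
  }
  truth <- dplyr::bind_rows(truth_rows)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(format = "rtnamer-phantom-cohort", version = 1L,
                   n_subjects = n_subjects, modality = modality,
                   config = unclass(config),
                   subjects = stats::setNames(as.list(scenarios_used), ids))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, truth = truth, subjects = ids))
}

#' Read a cohort ground-truth table
#' @param cohort_dir Cohort directory written by [generate_cohort()].
#' @return Tibble of the ground-truth CSV.
#' @export
read_cohort_truth <- function(cohort_dir) {
  df <- utils::read.csv(file.path(cohort_dir, "ground_truth.csv"),
                        stringsAsFactors = FALSE)
  df$roi_number <- as.integer(df$roi_number)
  df$class_id <- as.integer(df$class_id)
  tibble::as_tibble(df)
}
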