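#' Read a subject directory: image series + RT Structure Set
#'
#' Expects a directory holding one DICOM image series (CT or MR; used only to
#' define the voxel grid) and exactly one RT Structure Set. ROI names are
#' preserved as stored; empty ROIs (no contours) are parsed and flagged.
#'
#' @param subject_dir Path to the subject directory.
#' @return An `rtn_structure_set`: list with `subject_id`, `structures` (each
#'   an `rtn_structure` with `roi_number`, `name`, `contours`, `color`,
#'   `is_empty`), `geometry`, `source_modality`, and the parsed DICOM tree
#'   (`dicom`) needed by [write_renamed_copy()].
#' @export
read_structure_set <- function(subject_dir) {
  if (!dir.exists(subject_dir)) stop("no such directory: ", subject_dir, call. = FALSE)
  files <- list.files(subject_dir, full.names = TRUE)
  slices <- list()
  rtstructs <- list()
  for (f in files) {
    parsed <- tryCatch(dcm_read_file(f), error = function(e) NULL)
    if (is.null(parsed)) next
    modality <- dcm_string(dcm_find(parsed$dataset, 0x0008L, 0x0060L))
    if (identical(modality, "RTSTRUCT")) {
      rtstructs[[length(rtstructs) + 1L]] <- list(path = f, parsed = parsed)
    } else if (modality %in% c("CT", "MR")) {
      slices[[length(slices) + 1L]] <- parsed$dataset
    }
  }
  if (length(rtstructs) != 1) {
    stop(sprintf("expected exactly one RT Structure Set in %s, found %d",
                 subject_dir, length(rtstructs)), call. = FALSE)
  }
  if (length(slices) == 0) {
    stop("no image series found in ", subject_dir, call. = FALSE)
  }
  geometry <- series_geometry(slices)
  modality <- dcm_string(dcm_find(slices[[1]], 0x0008L, 0x0060L))
  parsed <- rtstructs[[1]]$parsed
  subject_id <- dcm_string(dcm_find(parsed$dataset, 0x0010L, 0x0020L))
  if (is.null(subject_id)) subject_id <- basename(subject_dir)

  structures <- parse_rtstruct_rois(parsed$dataset)
  roi_numbers <- vapply(structures, `[[`, integer(1), "roi_number")
  if (anyDuplicated(roi_numbers)) {
    stop("duplicate ROI numbers in structure set", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, structures = structures, geometry = geometry,
         source_modality = modality, dicom = parsed, path = rtstructs[[1]]$path),
    class = "rtn_structure_set"
  )
}

#' @export
print.rtn_structure_set <- function(x, ...) {
  cat(sprintf("<rtn_structure_set '%s': %d structures, %s series %dx%dx%d>\n",
              x$subject_id, length(x$structures), x$source_modality,
              x$geometry$dims[1], x$geometry$dims[2], x$geometry$dims[3]))
  invisible(x)
}

series_geometry <- function(slices) {
  pos <- t(vapply(slices, function(d) dcm_numeric(dcm_find(d, 0x0020L, 0x0032L)),
                  numeric(3)))
  orient <- t(vapply(slices, function(d) dcm_numeric(dcm_find(d, 0x0020L, 0x0037L)),
                     numeric(6)))
  if (any(abs(sweep(orient, 2, c(1, 0, 0, 0, 1, 0))) > 1e-6)) {
    stop("only axis-aligned axial image series are supported", call. = FALSE)
  }
  rows <- vapply(slices, function(d) dcm_u16(dcm_find(d, 0x0028L, 0x0010L)), integer(1))
  cols <- vapply(slices, function(d) dcm_u16(dcm_find(d, 0x0028L, 0x0011L)), integer(1))
  psp <- t(vapply(slices, function(d) dcm_numeric(dcm_find(d, 0x0028L, 0x0030L)),
                  numeric(2)))  # (row, col) spacing
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1 ||
      any(abs(sweep(psp, 2, psp[1, ])) > 1e-6)) {
    stop("inconsistent image series geometry", call. = FALSE)
  }
  ord <- order(pos[, 3])
  z <- pos[ord, 3]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3) {
      stop("inconsistent slice spacing in image series", call. = FALSE)
    }
    dz <- mean(dz)
  } else {
    thick <- dcm_numeric(dcm_find(slices[[1]], 0x0018L, 0x0050L))
    dz <- if (length(thick)) thick[1] else 1
  }
  if (any(abs(sweep(pos[, 1:2, drop = FALSE], 2, pos[1, 1:2])) > 1e-6)) {
    stop("image slices are not aligned in-plane", call. = FALSE)
  }
  image_geometry(origin = c(pos[ord[1], 1], pos[ord[1], 2], z[1]),
                 spacing = c(psp[1, 2], psp[1, 1], dz),
                 dims = c(rows[1], cols[1], length(slices)),
                 slice_z = z)
}

parse_rtstruct_rois <- function(dataset) {
  roi_seq <- dcm_find(dataset, 0x3006L, 0x0020L)
  contour_seq <- dcm_find(dataset, 0x3006L, 0x0039L)
  if (is.null(roi_seq)) stop("no StructureSetROISequence present", call. = FALSE)
  contours_by_roi <- list()
  colors_by_roi <- list()
  if (!is.null(contour_seq)) {
    for (item in contour_seq$value) {
      ref <- as.integer(dcm_numeric(dcm_find(item, 0x3006L, 0x0084L)))
      cs <- dcm_find(item, 0x3006L, 0x0040L)
      pts <- list()
      if (!is.null(cs)) {
        pts <- lapply(cs$value, function(ci) {
          dat <- dcm_numeric(dcm_find(ci, 0x3006L, 0x0050L))
          matrix(dat, ncol = 3, byrow = TRUE)
        })
      }
      contours_by_roi[[as.character(ref)]] <- pts
      col <- dcm_find(item, 0x3006L, 0x002AL)
      colors_by_roi[[as.character(ref)]] <-
        if (is.null(col)) c(255, 0, 0) else dcm_numeric(col)
    }
  }
  lapply(roi_seq$value, function(item) {
    roi_number <- as.integer(dcm_numeric(dcm_find(item, 0x3006L, 0x0022L)))
    name <- dcm_string(dcm_find(item, 0x3006L, 0x0026L))
    contours <- contours_by_roi[[as.character(roi_number)]]
    if (is.null(contours)) contours <- list()
    structure(list(roi_number = roi_number,
                   name = if (is.null(name)) "" else name,
                   contours = contours,
                   color = colors_by_roi[[as.character(roi_number)]],
                   is_empty = length(contours) == 0),
              class = "rtn_structure")
  })
}

#' Write a renamed copy of an RT Structure Set
#'
#' The output differs from the input only in the ROI name fields named by the
#' rename plan and a fresh SOP Instance UID (required for a new DICOM object);
#' contour data are carried over byte-identically. Names longer than the
#' DICOM LO limit (64 characters) are refused, never silently truncated.
#'
#' @param structure_set An `rtn_structure_set` from [read_structure_set()].
#' @param rename_plan Named character vector mapping ROI number (as name) to
#'   new structure name, or a data frame with columns `roi_number`,
#'   `new_name`.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_renamed_copy <- function(structure_set, rename_plan, out_path) {
  stopifnot(inherits(structure_set, "rtn_structure_set"))
  if (is.data.frame(rename_plan)) {
    plan <- stats::setNames(as.character(rename_plan$new_name),
                            as.character(rename_plan$roi_number))
  } else {
    plan <- rename_plan
  }
  if (length(plan) > 0 && (is.null(names(plan)) || any(!nzchar(names(plan))))) {
    stop("rename plan must be keyed by ROI number", call. = FALSE)
  }
  known <- vapply(structure_set$structures, `[[`, integer(1), "roi_number")
  bad <- setdiff(as.integer(names(plan)), known)
  if (length(bad) > 0) {
    stop("rename plan refers to unknown ROI number(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(plan))) stop("new names must be non-empty", call. = FALSE)
  too_long <- nchar(plan, type = "bytes") > 64
  if (any(too_long)) {
    stop("new name exceeds DICOM LO length (64): ",
         paste(plan[too_long], collapse = "; "), call. = FALSE)
  }

  dataset <- structure_set$dicom$dataset
  for (i in seq_along(dataset)) {
    el <- dataset[[i]]
    if (el$group == 0x3006L && el$element == 0x0020L) {
      items <- el$value
      for (k in seq_along(items)) {
        roi <- as.character(as.integer(dcm_numeric(dcm_find(items[[k]], 0x3006L, 0x0022L))))
        if (roi %in% names(plan)) {
          items[[k]] <- dcm_set(items[[k]], 0x3006L, 0x0026L, "LO", plan[[roi]])
        }
      }
      el$value <- items
      dataset[[i]] <- el
    }
  }
  old_uid <- dcm_string(dcm_find(dataset, 0x0008L, 0x0018L))
  uid <- new_sop_instance_uid(old_uid)
  dataset <- dcm_set(dataset, 0x0008L, 0x0018L, "UI", uid)
  sop_class <- dcm_string(dcm_find(dataset, 0x0008L, 0x0016L))
  if (is.null(sop_class)) sop_class <- UID_SOP_RTSTRUCT
  dcm_write_file(out_path, sop_class, uid, dataset)
  invisible(out_path)
}

# ---- writers used by the synthetic phantom generator ----------------------

random_uid <- function() {
  paste0("2.25.", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

# Writes one uniform-intensity image slice carrying only geometry.
write_image_slice <- function(path, geometry, k, modality, subject_id,
                              study_uid, series_uid, frame_uid) {
  rows <- geometry$dims[1]; cols <- geometry$dims[2]
  sop_class <- if (modality == "MR") UID_SOP_MR else UID_SOP_CT
  uid <- random_uid()
  dataset <- list(
    dcm_element(0x0008L, 0x0016L, "UI", sop_class),
    dcm_element(0x0008L, 0x0018L, "UI", uid),
    dcm_element(0x0008L, 0x0020L, "DA", "20240101"),
    dcm_element(0x0008L, 0x0030L, "TM", "000000"),
    dcm_element(0x0008L, 0x0060L, "CS", modality),
    dcm_element(0x0010L, 0x0010L, "PN", "Phantom^Synthetic"),
    dcm_element(0x0010L, 0x0020L, "LO", subject_id),
    dcm_element(0x0018L, 0x0050L, "DS", ds_fmt(geometry$spacing[3])),
    dcm_element(0x0020L, 0x000DL, "UI", study_uid),
    dcm_element(0x0020L, 0x000EL, "UI", series_uid),
    dcm_element(0x0020L, 0x0013L, "IS", as.character(k)),
    dcm_element(0x0020L, 0x0032L, "DS",
                c(ds_fmt(geometry$origin[1]), ds_fmt(geometry$origin[2]),
                  ds_fmt(geometry$slice_z[k]))),
    dcm_element(0x0020L, 0x0037L, "DS", c("1", "0", "0", "0", "1", "0")),
    dcm_element(0x0020L, 0x0052L, "UI", frame_uid),
    dcm_element(0x0028L, 0x0002L, "US", 1L),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0010L, "US", rows),
    dcm_element(0x0028L, 0x0011L, "US", cols),
    dcm_element(0x0028L, 0x0030L, "DS",
                c(ds_fmt(geometry$spacing[2]), ds_fmt(geometry$spacing[1]))),
    dcm_element(0x0028L, 0x0100L, "US", 16L),
    dcm_element(0x0028L, 0x0101L, "US", 16L),
    dcm_element(0x0028L, 0x0102L, "US", 15L),
    dcm_element(0x0028L, 0x0103L, "US", 0L),
    dcm_element(0x7FE0L, 0x0010L, "OW", raw(rows * cols * 2L))
  )
  dcm_write_file(path, sop_class, uid, dataset)
}

# Writes an RTSTRUCT for a list of structures:
# each list(roi_number, name, contours = list of n-by-3 matrices, color).
write_structure_file <- function(path, structures, subject_id,
                                 study_uid, frame_uid) {
  uid <- random_uid()
  roi_items <- lapply(structures, function(s) {
    list(
      dcm_element(0x3006L, 0x0022L, "IS", as.character(s$roi_number)),
      dcm_element(0x3006L, 0x0024L, "UI", frame_uid),
      dcm_element(0x3006L, 0x0026L, "LO", s$name)
    )
  })
  contour_items <- lapply(structures, function(s) {
    item <- list(
      dcm_element(0x3006L, 0x002AL, "IS",
                  as.character(if (is.null(s$color)) c(255, 0, 0) else s$color))
    )
    if (length(s$contours) > 0) {
      cs <- lapply(s$contours, function(pts) {
        list(
          dcm_element(0x3006L, 0x0042L, "CS", "CLOSED_PLANAR"),
          dcm_element(0x3006L, 0x0046L, "IS", as.character(nrow(pts))),
          dcm_element(0x3006L, 0x0050L, "DS", ds_fmt(as.vector(t(pts))))
        )
      })
      item <- c(item, list(dcm_element(0x3006L, 0x0040L, "SQ", cs)))
    }
    c(item, list(dcm_element(0x3006L, 0x0084L, "IS", as.character(s$roi_number))))
  })
  dataset <- list(
    dcm_element(0x0008L, 0x0016L, "UI", UID_SOP_RTSTRUCT),
    dcm_element(0x0008L, 0x0018L, "UI", uid),
    dcm_element(0x0008L, 0x0020L, "DA", "20240101"),
    dcm_element(0x0008L, 0x0030L, "TM", "000000"),
    dcm_element(0x0008L, 0x0060L, "CS", "RTSTRUCT"),
    dcm_element(0x0010L, 0x0010L, "PN", "Phantom^Synthetic"),
    dcm_element(0x0010L, 0x0020L, "LO", subject_id),
    dcm_element(0x0020L, 0x000DL, "UI", study_uid),
    dcm_element(0x0020L, 0x000EL, "UI", random_uid()),
    dcm_element(0x3006L, 0x0002L, "SH", "PhantomSS"),
    dcm_element(0x3006L, 0x0010L, "SQ",
                list(list(dcm_element(0x0020L, 0x0052L, "UI", frame_uid)))),
    dcm_element(0x3006L, 0x0020L, "SQ", roi_items),
    dcm_element(0x3006L, 0x0039L, "SQ", contour_items)
  )
  dcm_write_file(path, UID_SOP_RTSTRUCT, uid, dataset)
}

#' Extract the raw contour payloads of a structure set
#'
#' Convenience for integrity checks: returns, per ROI number, the list of raw
#' ContourData byte vectors exactly as stored in the file.
#'
#' @param structure_set An `rtn_structure_set`.
#' @return Named list (by ROI number) of lists of raw vectors.
#' @export
contour_payloads <- function(structure_set) {
  out <- list()
  cs <- dcm_find(structure_set$dicom$dataset, 0x3006L, 0x0039L)
  if (is.null(cs)) return(out)
  for (item in cs$value) {
    ref <- as.character(as.integer(dcm_numeric(dcm_find(item, 0x3006L, 0x0084L))))
    seqel <- dcm_find(item, 0x3006L, 0x0040L)
    out[[ref]] <- if (is.null(seqel)) list() else
      lapply(seqel$value, function(ci) dcm_find(ci, 0x3006L, 0x0050L)$value)
  }
  out
}
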