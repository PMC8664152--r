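#' Image geometry of an axial series
#'
#' Describes the voxel grid a structure set is rasterized on: origin (patient
#' coordinates of the first voxel center, mm), spacing (column x, row y,
#' slice z, mm) and dimensions (rows, columns, slices). Only axis-aligned
#' axial series are supported; masks are stored index-ordered
#' (row, column, slice) with rows along the patient y axis and columns along
#' x (DICOM LPS).
#'
#' @param origin Numeric triplet (x, y, z) in mm.
#' @param spacing Numeric triplet (x, y, z) in mm, strictly positive.
#' @param dims Integer triplet (rows, columns, slices), strictly positive.
#' @param slice_z Optional vector of slice z positions (defaults to a uniform
#'   grid from `origin[3]` with step `spacing[3]`).
#' @return An `rtn_geometry` object.
#' @export
image_geometry <- function(origin, spacing, dims, slice_z = NULL) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3)
  if (any(spacing <= 0)) stop("spacing components must be strictly positive", call. = FALSE)
  if (any(dims <= 0)) stop("dimensions must be strictly positive", call. = FALSE)
  if (is.null(slice_z)) slice_z <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  stopifnot(length(slice_z) == dims[3])
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 slice_z = as.numeric(slice_z)),
            class = "rtn_geometry")
}

#' @export
print.rtn_geometry <- function(x, ...) {
  cat(sprintf("<rtn_geometry %dx%dx%d @ %.3gx%.3gx%.3g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

new_mask <- function(grid) {
  structure(list(grid = grid, foreground_count = sum(grid)), class = "rtn_mask")
}

#' @export
print.rtn_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<rtn_mask %dx%dx%d, %d foreground voxels>\n",
              d[1], d[2], d[3], x$foreground_count))
  invisible(x)
}

# Even-odd polygon fill on pixel centers within the polygon bounding box.
# Returns row/column index pairs of interior pixels. A pixel belongs to the
# polygon iff its center is strictly inside under the crossing-number rule.
poly_fill_idx <- function(poly, geometry) {
  ox <- geometry$origin[1]; oy <- geometry$origin[2]
  sx <- geometry$spacing[1]; sy <- geometry$spacing[2]
  nr <- geometry$dims[1]; nc <- geometry$dims[2]
  xs <- poly[, 1]; ys <- poly[, 2]
  jmin <- max(1L, ceiling((min(xs) - ox) / sx) + 1L)
  jmax <- min(nc, floor((max(xs) - ox) / sx) + 1L)
  imin <- max(1L, ceiling((min(ys) - oy) / sy) + 1L)
  imax <- min(nr, floor((max(ys) - oy) / sy) + 1L)
  if (jmin > jmax || imin > imax) return(cbind(i = integer(0), j = integer(0)))
  xc <- ox + (seq(jmin, jmax) - 1) * sx
  yc <- oy + (seq(imin, imax) - 1) * sy
  ni <- length(yc); nj <- length(xc)
  cross <- matrix(0L, ni, nj)
  n <- nrow(poly)
  x2 <- xs[c(2:n, 1L)]; y2 <- ys[c(2:n, 1L)]
  for (e in seq_len(n)) {
    if (ys[e] == y2[e]) next
    spans <- (ys[e] > yc) != (y2[e] > yc)
    if (!any(spans)) next
    xint <- (x2[e] - xs[e]) * (yc - ys[e]) / (y2[e] - ys[e]) + xs[e]
    cross <- cross + (spans * outer(xint, xc, ">"))
  }
  inside <- which(cross %% 2L == 1L, arr.ind = TRUE)
  cbind(i = inside[, 1L] + imin - 1L, j = inside[, 2L] + jmin - 1L)
}

#' Rasterize an RT structure to a 3D binary mask
#'
#' Each planar contour is filled on its own slice; a voxel is foreground iff
#' its center lies inside the polygon. Multiple polygons on one slice combine
#' by the even-odd rule (so inner rings create holes); `fill_rule = "union"`
#' switches to a plain union. Contours are not interpolated between slices.
#'
#' @param struct An `rtn_structure` (as returned inside
#'   [read_structure_set()]), or any list with a `contours` field holding
#'   n-by-3 point matrices in mm.
#' @param geometry An [image_geometry()].
#' @param fill_rule `"evenodd"` (default) or `"union"`.
#' @return An `rtn_mask`: list with the logical `grid` array (rows, columns,
#'   slices) and `foreground_count`.
#' @export
rasterize <- function(struct, geometry, fill_rule = c("evenodd", "union")) {
  fill_rule <- match.arg(fill_rule)
  stopifnot(inherits(geometry, "rtn_geometry"))
  grid <- array(FALSE, geometry$dims)
  cache <- new.env(parent = emptyenv())
  dz <- geometry$spacing[3]
  for (contour in struct$contours) {
    if (is.null(dim(contour)) || nrow(contour) < 3) {
      warning("degenerate contour (<3 points) skipped", call. = FALSE)
      next
    }
    z <- contour[1, 3]
    k <- which.min(abs(geometry$slice_z - z))
    if (abs(geometry$slice_z[k] - z) > dz / 2 + 1e-6) {
      warning("contour outside image volume clipped", call. = FALSE)
      next
    }
    key <- paste(c(contour[, 1], contour[, 2]), collapse = ",")
    idx <- cache[[key]]
    if (is.null(idx)) {
      idx <- poly_fill_idx(contour[, 1:2, drop = FALSE], geometry)
      cache[[key]] <- idx
    }
    if (nrow(idx) == 0) next
    lin <- idx[, 1L] + (idx[, 2L] - 1L) * geometry$dims[1] +
      (k - 1L) * geometry$dims[1] * geometry$dims[2]
    if (fill_rule == "evenodd") {
      grid[lin] <- !grid[lin]
    } else {
      grid[lin] <- TRUE
    }
  }
  new_mask(grid)
}

#' Structure volume from a binary mask
#'
#' @param mask An `rtn_mask` aligned to `geometry`.
#' @param geometry The [image_geometry()] the mask lives on.
#' @return Volume in cm^3 (foreground voxel count times voxel volume).
#' @export
structure_volume <- function(mask, geometry) {
  stopifnot(inherits(mask, "rtn_mask"), inherits(geometry, "rtn_geometry"))
  mask$foreground_count * prod(geometry$spacing) / 1000
}
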