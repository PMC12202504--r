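#' Read a CT volume from a NIfTI file
#'
#' Reads a 3-D scalar NIfTI image (`.nii` or `.nii.gz`) into an
#' [image_grid()]. Values are converted to double HU regardless of the
#' on-disk type. Voxel spacing is taken from the header `pixdim`; the origin
#' is the translation part of the sform/qform. 4-D inputs whose trailing axes
#' are singletons are squeezed to 3-D.
#'
#' Only axis-aligned geometries are supported: an affine whose rotation part
#' has off-diagonal terms beyond `1e-3` (relative to the voxel size) is
#' rejected, so that physical-distance computations stay unambiguous.
#'
#' @param path path to a readable NIfTI file.
#' @return An [image_grid()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) < 3L)
    stop("NIfTI payload in ", path, " is not a 3-D image (dim field: ",
         paste(d, collapse = "x"), ")")
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("header field pixdim declares non-positive spacing (",
         paste(format(spacing), collapse = ", "), ") in ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4))) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-3 * max(spacing)))
      stop("header affine (sform/qform) is not axis-aligned in ", path,
           "; oblique acquisitions are not supported")
    origin <- xf[1:3, 4]
  }
  image_grid(as.array(img), spacing = spacing, origin = origin)
}

#' Read a binary mask from a NIfTI file
#'
#' As [load_volume()], but the payload must be 0/1 and is returned as a
#' [binary_mask()].
#'
#' @inheritParams load_volume
#' @return A [binary_mask()].
#' @export
load_mask <- function(path) {
  g <- load_volume(path)
  binary_mask(g$values != 0, spacing = g$spacing, origin = g$origin)
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are written as float32 HU; masks as uint8 0/1. Spacing and origin
#' are recorded in both `pixdim` and a diagonal sform, so a round-trip through
#' [load_volume()] preserves the geometry.
#'
#' @param x an [image_grid()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_grid") || inherits(x, "binary_mask"))
  vals <- if (is.logical(x$values)) {
    a <- array(as.integer(x$values), dim = dim(x$values)); a
  } else x$values
  img <- RNifti::asNifti(vals)
  m <- diag(c(x$spacing, 1))
  m[1:3, 4] <- x$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, x$spacing)
  dt <- if (is.logical(x$values)) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

#' Clear a box-shaped region from a mask
#'
#' Returns a copy of the mask with every voxel inside the given axis-aligned
#' box cleared, leaving the input untouched. Intended for manual exclusion of
#' regions such as metal-artifact neighbourhoods around stent grafts.
#'
#' The box uses half-open 0-based index ranges per axis (the convention of
#' most image-processing toolkits): voxel index `i` (0-based) is inside when
#' `lo <= i < hi`. A degenerate box with `lo == hi` on any axis clears
#' nothing. Ranges are clamped to the lattice; a box lying entirely outside
#' it is an error, to catch coordinate mistakes.
#'
#' @param mask a [binary_mask()].
#' @param box list with numeric(3) elements `lo` and `hi` (0-based, half-open).
#' @return A new [binary_mask()].
#' @export
exclude_region <- function(mask, box) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.list(box) || !all(c("lo", "hi") %in% names(box)))
    stop("'box' must be list(lo = c(x,y,z), hi = c(x,y,z))")
  lo <- as.numeric(box$lo); hi <- as.numeric(box$hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(hi < lo)) stop("box has hi < lo")
  d <- dim(mask$values)
  if (any(lo >= d) || any(hi <= 0))
    stop("exclusion box lies entirely outside the lattice (shape ",
         paste(d, collapse = "x"), ")")
  cl <- pmax(lo, 0); ch <- pmin(hi, d)
  out <- mask$values
  if (all(ch > cl)) {
    out[(cl[1] + 1):ch[1], (cl[2] + 1):ch[2], (cl[3] + 1):ch[3]] <- FALSE
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}

#' Per-slice centroid centerline of a mask
#'
#' The centerline is the polyline of mask centroids of each slice along the
#' given axis (default: the acquisition axis, 3), in world millimetres;
#' slices containing no mask voxels are skipped. Cumulative Euclidean
#' arc-length along the polyline parameterises the vessel, with arc-length 0
#' at the first non-empty slice. This centroid polyline is a deliberate
#' approximation to dedicated centerline-extraction software.
#'
#' @param mask a [binary_mask()].
#' @param axis slice axis (1, 2 or 3; default 3).
#' @return data.frame with columns `slice` (1-based index), `x_mm`, `y_mm`,
#'   `z_mm` (centroid world coordinates) and `arclength_mm`.
#' @export
centerline <- function(mask, axis = 3L) {
  stopifnot(inherits(mask, "binary_mask"), axis %in% 1:3)
  d <- dim(mask$values)
  keep <- which(apply(mask$values, axis, any))
  if (length(keep) == 0L) stop("mask is empty: no centerline")
  other <- setdiff(1:3, axis)
  cent <- t(vapply(keep, function(s) {
    idx <- switch(axis,
      which(mask$values[s, , , drop = FALSE], arr.ind = TRUE),
      which(mask$values[, s, , drop = FALSE], arr.ind = TRUE),
      which(mask$values[, , s, drop = FALSE], arr.ind = TRUE))
    ctr <- colMeans(idx)          # 1-based fractional indices, slice axis = s
    ctr[axis] <- s
    mask$origin + (ctr - 1) * mask$spacing
  }, numeric(3)))
  steps <- if (length(keep) > 1L)
    sqrt(rowSums(diff(cent)^2)) else numeric(0)
  data.frame(slice = keep, x_mm = cent[, 1], y_mm = cent[, 2],
             z_mm = cent[, 3], arclength_mm = c(0, cumsum(steps)))
}

#' Crop a volume and mask to an arc-length range along the centerline
#'
#' Defines the quantitative analysis range of the vessel: slices whose
#' centroid-centerline arc-length falls inside `[lo_mm, hi_mm]` are kept;
#' the volume and mask are cropped identically along the slice axis.
#'
#' @param grid an [image_grid()].
#' @param mask a non-empty [binary_mask()] aligned with `grid`.
#' @param lo_mm,hi_mm arc-length bounds in mm; `0 <= lo_mm < hi_mm`.
#' @param axis slice axis (default 3).
#' @return list with cropped `grid`, `mask`, and the kept `slices`.
#' @export
crop_range <- function(grid, mask, lo_mm, hi_mm, axis = 3L) {
  assert_aligned(grid, mask)
  if (!(is.numeric(lo_mm) && is.numeric(hi_mm) && lo_mm >= 0 && lo_mm < hi_mm))
    stop("analysis range must satisfy 0 <= lo_mm < hi_mm")
  cl <- centerline(mask, axis = axis)
  keep <- cl$slice[cl$arclength_mm >= lo_mm & cl$arclength_mm <= hi_mm]
  if (length(keep) == 0L)
    stop("analysis range [", lo_mm, ", ", hi_mm,
         "] mm selects no slice (centerline spans 0..",
         format(max(cl$arclength_mm)), " mm)")
  gv <- slab(grid$values, axis, keep)
  mv <- slab(mask$values, axis, keep)
  origin <- grid$origin
  origin[axis] <- origin[axis] + (min(keep) - 1) * grid$spacing[axis]
  list(grid = image_grid(gv, spacing = grid$spacing, origin = origin),
       mask = binary_mask(mv, spacing = mask$spacing, origin = origin),
       slices = keep)
}

# subset an array along one axis, keeping dimensions
slab <- function(a, axis, idx) {
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE])
}
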