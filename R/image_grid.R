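#' Construct an image grid
#'
#' An `image_grid` is a 3-D scalar field of CT attenuation values (Hounsfield
#' units) on a regular lattice with per-axis voxel spacing in millimetres and
#' a world-space origin. Values are always stored as double so that
#' region means are not quantised by integer file types.
#'
#' The world coordinate of the voxel with (1-based) array index `i` along an
#' axis is `origin + (i - 1) * spacing` for that axis; the lattice is
#' axis-aligned by construction.
#'
#' @param values 3-D numeric array of HU values; all values must be finite.
#' @param spacing numeric(3), voxel spacing in mm per axis; all positive.
#' @param origin numeric(3), world coordinate (mm) of the first voxel.
#' @return An object of class `image_grid` with elements `values`, `spacing`,
#'   `origin`.
#' @export
image_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- squeeze_to_3d(values)
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm), got: ",
         paste(format(spacing), collapse = ", "))
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  if (any(dim(values) < 1L)) stop("lattice must have at least 1 voxel per axis")
  if (any(!is.finite(values))) stop("HU values must all be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' Construct a binary mask on an image grid geometry
#'
#' A `binary_mask` annotates an [image_grid()] geometry with a logical value
#' per voxel (e.g. the aortic mask, a perivascular ring, or a fat mask). The
#' mask carries its own copy of the grid geometry so that alignment with a
#' volume can always be verified.
#'
#' @param values 3-D logical (or 0/1 numeric) array.
#' @param spacing,origin grid geometry, as for [image_grid()]; alternatively
#'   pass `grid` to copy geometry from an existing `image_grid`.
#' @param grid optional `image_grid` whose geometry the mask annotates.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        grid = NULL) {
  values <- squeeze_to_3d(values)
  if (!is.logical(values)) {
    bad <- !(values %in% c(0, 1))
    if (any(bad)) stop("mask payload must be logical or 0/1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "image_grid"))
    spacing <- grid$spacing
    origin <- grid$origin
    if (!identical(dim(values), dim(grid$values)))
      stop("mask shape ", paste(dim(values), collapse = "x"),
           " does not match grid shape ",
           paste(dim(grid$values), collapse = "x"))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "binary_mask")
}

# Drop singleton trailing axes beyond the third (e.g. a 4-D NIfTI with one
# volume) and promote 2-D input to a single-slice 3-D lattice.
squeeze_to_3d <- function(values) {
  if (is.null(dim(values))) stop("expected an array, got a vector")
  d <- dim(values)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(values) <- d[1:3]
    } else {
      stop("payload is ", length(d), "-D with non-singleton trailing axes (",
           paste(d, collapse = "x"), "); expected a 3-D scalar image")
    }
  } else if (length(d) == 2L) {
    dim(values) <- c(d, 1L)
  }
  values
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(dim(x$values), collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = ", "), "\n")
  cat("  origin  (mm):", paste(format(x$origin), collapse = ", "), "\n")
  cat("  HU range:", format(min(x$values)), "..", format(max(x$values)), "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(dim(x$values), collapse = " x "), "voxels,",
      sum(x$values), "set\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = ", "), "\n")
  invisible(x)
}

#' Check that a volume and a mask share the same lattice geometry
#'
#' Shapes must match exactly and spacings must agree within `tol` millimetres
#' on every axis. The verdict object lists each mismatching axis, so a failed
#' check can be reported precisely rather than as a bare FALSE.
#'
#' @param grid an [image_grid()].
#' @param mask a [binary_mask()].
#' @param tol spacing tolerance in mm (default `1e-4`).
#' @return A list of class `alignment_check` with elements `ok` (logical) and
#'   `failures` (character vector, empty when aligned).
#' @export
check_aligned <- function(grid, mask, tol = 1e-4) {
  stopifnot(inherits(grid, "image_grid"), inherits(mask, "binary_mask"))
  failures <- character(0)
  dg <- dim(grid$values); dm <- dim(mask$values)
  for (ax in 1:3) {
    if (dg[ax] != dm[ax])
      failures <- c(failures, sprintf(
        "axis %d: shape %d (grid) vs %d (mask)", ax, dg[ax], dm[ax]))
    if (abs(grid$spacing[ax] - mask$spacing[ax]) > tol)
      failures <- c(failures, sprintf(
        "axis %d: spacing %.6f mm (grid) vs %.6f mm (mask)",
        ax, grid$spacing[ax], mask$spacing[ax]))
  }
  structure(list(ok = length(failures) == 0L, failures = failures),
            class = "alignment_check")
}

#' @export
print.alignment_check <- function(x, ...) {
  if (x$ok) cat("aligned\n")
  else cat("NOT aligned:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

# internal: stop unless aligned
assert_aligned <- function(grid, mask, what = "mask") {
  chk <- check_aligned(grid, mask)
  if (!chk$ok)
    stop(what, " is not aligned with the volume: ",
         paste(chk$failures, collapse = "; "))
  invisible(TRUE)
}
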