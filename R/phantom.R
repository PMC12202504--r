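#' Specification of a synthetic CT phantom
#'
#' Describes a contrast-filled vessel running through the volume along the
#' slice axis, surrounded by a wall, two adipose shells at configurable
#' radial offsets from the vessel surface, and interstitial soft tissue
#' elsewhere. The centerline is either straight or helical (to exercise
#' arc-length computations). Compartment attenuations are means in HU, with
#' optional additive Gaussian noise.
#'
#' @param shape integer(3) lattice shape (default `c(48, 48, 60)`).
#' @param spacing numeric(3) voxel spacing in mm (default 1 mm isotropic).
#' @param centerline `"straight"` or `"helical"`.
#' @param helix_radius_mm,helix_pitch_mm helix geometry (used only for
#'   `"helical"`): in-plane radius and the z-distance of one full turn.
#' @param lumen_radius_mm,wall_thickness_mm vessel geometry (mm).
#' @param hu_lumen,hu_wall,hu_fat_close,hu_fat_distant,hu_background
#'   compartment HU means. Defaults: contrast-filled lumen +300, wall +40,
#'   close shell -70, distant shell -80, soft tissue +20. Fat shell means
#'   must lie inside `window`.
#' @param shells a [ring_spec()] giving the radial extents (mm) of the two
#'   adipose shells; defaults to the analysis rings so that ring extraction
#'   recovers the shells exactly.
#' @param window the [fat_window()] the shell means must respect.
#' @param noise_sd additive Gaussian noise SD in HU (default 0).
#' @param seed integer seed for the noise realisation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 60L), spacing = c(1, 1, 1),
                         centerline = c("straight", "helical"),
                         helix_radius_mm = 5, helix_pitch_mm = 40,
                         lumen_radius_mm = 5, wall_thickness_mm = 2,
                         hu_lumen = 300, hu_wall = 40,
                         hu_fat_close = -70, hu_fat_distant = -80,
                         hu_background = 20,
                         shells = ring_spec(), window = fat_window(),
                         noise_sd = 0, seed = 1L) {
  centerline <- match.arg(centerline)
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(spacing) == 3L, all(spacing > 0),
            lumen_radius_mm > 0, wall_thickness_mm >= 0, noise_sd >= 0)
  for (hu in c(hu_fat_close, hu_fat_distant))
    if (hu < window$lo_hu || hu > window$hi_hu)
      stop("fat shell mean ", hu, " HU lies outside the fat window [",
           window$lo_hu, ", ", window$hi_hu, "]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 centerline = centerline, helix_radius_mm = helix_radius_mm,
                 helix_pitch_mm = helix_pitch_mm,
                 lumen_radius_mm = lumen_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 hu_lumen = hu_lumen, hu_wall = hu_wall,
                 hu_fat_close = hu_fat_close,
                 hu_fat_distant = hu_fat_distant,
                 hu_background = hu_background,
                 shells = shells, window = window,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Builds the HU volume and the vessel mask described by a [phantom_spec()],
#' together with a ground-truth record: per-shell voxel counts and the exact
#' per-shell mean HU after the noise realisation. The vessel cross-section is
#' circular in each slice around the (possibly helical) centerline; the
#' adipose shells are placed by the same surface-distance geometry that the
#' quantification uses, so on a noiseless phantom the pipeline recovers the
#' configured shell means exactly.
#'
#' Deterministic given `spec$seed`. Errors if the distant shell would be
#' clipped by the lateral lattice boundary.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid` ([image_grid()]), `mask` (vessel [binary_mask()])
#'   and `truth` (list: configured means, realised shell means, voxel counts,
#'   and the generating specification).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  # world coordinates of voxel centers (origin at 0)
  xs <- (seq_len(nx) - 1) * sp[1]
  ys <- (seq_len(ny) - 1) * sp[2]
  cx0 <- mean(range(xs)); cy0 <- mean(range(ys))

  # per-slice centerline position
  zmm <- (seq_len(nz) - 1) * sp[3]
  if (spec$centerline == "helical") {
    ang <- 2 * pi * zmm / spec$helix_pitch_mm
    cx <- cx0 + spec$helix_radius_mm * cos(ang)
    cy <- cy0 + spec$helix_radius_mm * sin(ang)
  } else {
    cx <- rep(cx0, nz); cy <- rep(cy0, nz)
  }

  # in-plane radial distance to the slice's centerline point
  mask <- array(FALSE, dim = d)
  lumen <- array(FALSE, dim = d)
  r_out <- spec$lumen_radius_mm + spec$wall_thickness_mm
  for (k in seq_len(nz)) {
    r2 <- outer((xs - cx[k])^2, (ys - cy[k])^2, `+`)
    mask[, , k] <- r2 <= r_out^2
    lumen[, , k] <- r2 <= spec$lumen_radius_mm^2
  }
  if (!any(mask)) stop("vessel mask is empty; enlarge the lattice")
  bm <- binary_mask(mask, spacing = sp)

  dist <- surface_distance_map(bm)
  sh <- spec$shells
  close_v <- dist >= sh$close_lo_mm & dist <= sh$close_hi_mm
  distant_v <- dist >= sh$distant_lo_mm & dist <= sh$distant_hi_mm & !close_v

  # the distant shell must fit radially inside the lattice
  lateral <- array(FALSE, dim = d)
  lateral[c(1, nx), , ] <- TRUE
  lateral[, c(1, ny), ] <- TRUE
  if (any(dist[lateral] <= sh$distant_hi_mm))
    stop("adipose shells exceed the lateral lattice bounds; ",
         "enlarge 'shape' or shrink the vessel/shell radii")

  hu <- array(spec$hu_background, dim = d)
  hu[mask] <- spec$hu_wall
  hu[lumen] <- spec$hu_lumen
  hu[close_v] <- spec$hu_fat_close
  hu[distant_v] <- spec$hu_fat_distant

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }

  truth <- list(
    n_close = sum(close_v), n_distant = sum(distant_v),
    mean_close_configured = spec$hu_fat_close,
    mean_distant_configured = spec$hu_fat_distant,
    mean_close_realised = mean(hu[close_v]),
    mean_distant_realised = mean(hu[distant_v]),
    spec = spec)

  list(grid = image_grid(hu, spacing = sp), mask = bm, truth = truth)
}

#' Write a phantom to paired NIfTI files with a JSON ground-truth sidecar
#'
#' @param phantom output of [make_phantom()].
#' @param prefix output path prefix; writes `<prefix>_ct.nii.gz`,
#'   `<prefix>_mask.nii.gz` and `<prefix>_truth.json`.
#' @return The three paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  ct <- paste0(prefix, "_ct.nii.gz")
  mk <- paste0(prefix, "_mask.nii.gz")
  tj <- paste0(prefix, "_truth.json")
  write_volume(phantom$grid, ct)
  write_mask(phantom$mask, mk)
  truth <- phantom$truth
  truth$spec <- lapply(unclass(truth$spec), function(x)
    if (inherits(x, "ring_spec") || inherits(x, "fat_window")) unclass(x) else x)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(ct = ct, mask = mk, truth = tj))
}
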