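# Per-fraction dose from a helical plan sinogram.  The roll recorded at
# treatment is applied as a gantry-angle offset on every control point, and
# the attenuation depth of each beamlet comes from the composite dual ray
# trace.  The beamlet dose model is a documented simplification
# (exponential attenuation in WEPL, inverse-square fall-off, Gaussian
# lateral leaf profile); it is interface-compatible with a full
# convolution/superposition engine but makes no claim to absolute clinical
# accuracy.

#' Helical plan
#'
#' A simplified helical-tomotherapy delivery description: the sinogram of
#' leaf-open fractions per projection plus the geometry needed to expand
#' projections into control points.
#'
#' @param leaf_open matrix `[projection, leaf]` of open-time fractions in
#'   `[0, 1]`; rows span `projections_per_rotation * n_rotations`.
#' @param projections_per_rotation projections per gantry rotation
#'   (default 51).
#' @param pitch couch travel per rotation, mm.
#' @param gantry_start starting gantry angle, degrees.
#' @param couch_start couch z at the first projection, mm.
#' @param n_leaves number of binary MLC leaves (default 64).
#' @param leaf_width_at_iso leaf width at the isocentre, mm (default 6.25).
#' @param fan_extent SI extent (jaw width) of the fan at the isocentre, mm.
#' @param source_axis_distance source-axis distance, mm (default 850).
#' @param output_factor Gy per unit open-time at zero depth, distance SAD,
#'   zero lateral offset.
#' @param dose_scale prescribed per-fraction dose scale factor.
#' @param mu_eff_cm effective linear attenuation coefficient, cm^-1.
#' @param isocentre in-plane (x, y) isocentre, mm.
#' @return object of class `helical_plan`.
#' @export
helical_plan <- function(leaf_open, projections_per_rotation = 51,
                         pitch = 15, gantry_start = 0, couch_start = 0,
                         n_leaves = 64, leaf_width_at_iso = 6.25,
                         fan_extent = 25, source_axis_distance = 850,
                         output_factor = 1, dose_scale = 1,
                         mu_eff_cm = 0.05, isocentre = c(0, 0)) {
  leaf_open <- as.matrix(leaf_open)
  if (any(leaf_open < 0 | leaf_open > 1))
    stop("leaf_open values must lie in [0, 1]")
  if (pitch < 0) stop("pitch must be non-negative")
  if (projections_per_rotation < 1) stop("need >= 1 projection per rotation")
  if (ncol(leaf_open) != n_leaves)
    stop("leaf_open must have n_leaves columns")
  n_rotations <- nrow(leaf_open) / projections_per_rotation
  structure(list(leaf_open = leaf_open,
                 projections_per_rotation = projections_per_rotation,
                 n_rotations = n_rotations,
                 pitch = pitch, gantry_start = gantry_start,
                 couch_start = couch_start, n_leaves = n_leaves,
                 leaf_width_at_iso = leaf_width_at_iso,
                 fan_extent = fan_extent,
                 source_axis_distance = source_axis_distance,
                 output_factor = output_factor, dose_scale = dose_scale,
                 mu_eff_cm = mu_eff_cm, isocentre = as.numeric(isocentre)),
            class = "helical_plan")
}

#' Write / read a helical plan as a structured text file
#'
#' Scalar fields appear as `key: value` lines; the sinogram follows a
#' `leaf_open:` marker as one whitespace-separated row per projection.
#'
#' @param plan a [helical_plan()].
#' @param path output file.
#' @return `write_plan`: the path, invisibly; `read_plan`: a
#'   [helical_plan()].
#' @export
write_plan <- function(plan, path) {
  scalars <- c("projections_per_rotation", "pitch", "gantry_start",
               "couch_start", "n_leaves", "leaf_width_at_iso", "fan_extent",
               "source_axis_distance", "output_factor", "dose_scale",
               "mu_eff_cm")
  lines <- vapply(scalars, function(k)
    sprintf("%s: %.10g", k, plan[[k]]), character(1))
  lines <- c(lines,
             sprintf("isocentre: %.10g %.10g", plan$isocentre[1],
                     plan$isocentre[2]),
             "leaf_open:",
             apply(plan$leaf_open, 1, function(r)
               paste(sprintf("%.6g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  marker <- which(lines == "leaf_open:")
  if (!length(marker)) stop("plan file has no leaf_open section: ", path)
  kv <- lines[seq_len(marker - 1)]
  keys <- sub(":.*", "", kv)
  vals <- sub("^[^:]*: *", "", kv)
  get <- function(k) as.numeric(strsplit(vals[match(k, keys)], " +")[[1]])
  mat <- do.call(rbind, lapply(lines[-seq_len(marker)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  helical_plan(mat,
               projections_per_rotation = get("projections_per_rotation"),
               pitch = get("pitch"), gantry_start = get("gantry_start"),
               couch_start = get("couch_start"), n_leaves = get("n_leaves"),
               leaf_width_at_iso = get("leaf_width_at_iso"),
               fan_extent = get("fan_extent"),
               source_axis_distance = get("source_axis_distance"),
               output_factor = get("output_factor"),
               dose_scale = get("dose_scale"), mu_eff_cm = get("mu_eff_cm"),
               isocentre = get("isocentre"))
}

#' Expand a plan into control points, applying roll as a gantry offset
#'
#' Each projection is subdivided into `n_sub` control points (seven by
#' default) uniformly spanning its gantry arc and couch travel, each
#' carrying 1/`n_sub` of the projection's open time.  Every gantry angle is
#' incremented by the recorded roll, exactly mimicking the in-treatment
#' compensation.
#'
#' @param plan a [helical_plan()].
#' @param roll roll in degrees.
#' @param n_sub subprojections per projection (default 7).
#' @return data frame with columns `projection`, `angle` (deg), `couch_z`
#'   (mm), `weight`.
#' @export
expand_control_points <- function(plan, roll = 0, n_sub = 7) {
  if (n_sub < 1) stop("n_sub must be >= 1")
  nproj <- nrow(plan$leaf_open)
  dang <- 360 / plan$projections_per_rotation
  dz <- plan$pitch / plan$projections_per_rotation
  # subprojection centres within one projection: (k - 1/2)/n_sub, k=1..n_sub
  frac <- (seq_len(n_sub) - 0.5) / n_sub
  proj <- rep(seq_len(nproj), each = n_sub)
  off <- rep(frac, times = nproj)
  data.frame(projection = proj,
             angle = plan$gantry_start + (proj - 1 + off) * dang + roll,
             couch_z = plan$couch_start + (proj - 1 + off) * dz,
             weight = rep(1 / n_sub, nproj * n_sub))
}

#' Dose from a single beamlet (simplified model)
#'
#' `dose = output_factor * open_fraction * exp(-mu_eff * wepl) *
#' (SAD / distance)^2 * exp(-offset^2 / (2 sigma^2))` with
#' `sigma = leaf_width / 2.355` (FWHM equal to one leaf width).  At zero
#' depth, distance SAD and zero offset an open beamlet delivers exactly the
#' output factor.
#'
#' @param open_fraction leaf open-time fraction in `[0, 1]`.
#' @param wepl_mm water-equivalent depth, mm.
#' @param source_distance_mm distance from source to point, mm.
#' @param lateral_offset_mm offset from the beamlet centre at the
#'   isocentre plane, mm.
#' @param plan a [helical_plan()] supplying the beam constants.
#' @return dose in Gy.
#' @export
beamlet_dose <- function(open_fraction, wepl_mm, source_distance_mm,
                         lateral_offset_mm, plan) {
  sigma <- plan$leaf_width_at_iso / 2.355
  plan$output_factor * open_fraction *
    exp(-plan$mu_eff_cm * wepl_mm / 10) *
    (plan$source_axis_distance / source_distance_mm)^2 *
    exp(-lateral_offset_mm^2 / (2 * sigma^2))
}

#' Compute the dose cube for one fraction
#'
#' Sums the beamlet model over all control points and leaves whose fan
#' covers each grid point, using the composite dual ray trace for the
#' water-equivalent depth.  The grid is derived from the MV image by
#' [make_dose_grid()].
#'
#' @param plan a [helical_plan()].
#' @param mv the MV [image_volume()].
#' @param masked_kv the aligned, masked kV volume (or `NULL` to trace the
#'   MV/planning image alone).
#' @param reg the fraction's [registration()]; an unusable fraction is
#'   refused.
#' @param cal_mv,cal_kv calibration lines for the two volumes.
#' @param downsample in-plane downsampling factor (power of 2).
#' @param n_sub subprojections per projection.
#' @return a [dose_cube()].
#' @export
compute_fraction_dose <- function(plan, mv, masked_kv = NULL,
                                  reg = registration(),
                                  cal_mv, cal_kv = kv_calibration(),
                                  downsample = 2, n_sub = 7) {
  if (!reg$usable)
    stop("fraction skipped: registration flagged unusable")
  grid <- make_dose_grid(mv, downsample)
  cp <- expand_control_points(plan, roll = reg$roll, n_sub = n_sub)
  pts <- as.matrix(expand.grid(y = grid$y, x = grid$x, z = grid$z))
  pts <- pts[, c("x", "y", "z")]
  beam <- list(sad = plan$source_axis_distance, mu_cm = plan$mu_eff_cm,
               output_factor = plan$output_factor,
               dose_scale = plan$dose_scale, n_leaves = plan$n_leaves,
               leaf_width = plan$leaf_width_at_iso,
               fan_extent = plan$fan_extent,
               iso_x = plan$isocentre[1], iso_y = plan$isocentre[2])
  leaf_cp <- plan$leaf_open[cp$projection, , drop = FALSE]
  mv_org <- c(mv$origin, mv$slice_positions[1])
  mv_sp <- c(mv$pixel_spacing[2], mv$pixel_spacing[1], slice_spacing(mv))
  use_kv <- !is.null(masked_kv)
  if (use_kv) {
    kv_org <- c(masked_kv$origin, masked_kv$slice_positions[1])
    kv_sp <- c(masked_kv$pixel_spacing[2], masked_kv$pixel_spacing[1],
               slice_spacing(masked_kv))
    kv_vox <- masked_kv$voxels
    kco <- cal_kv$offset; kcs <- cal_kv$slope
  } else {
    kv_org <- kv_sp <- c(0, 0, 0); kv_vox <- array(0, c(1, 1, 1))
    kco <- 0; kcs <- 1000
  }
  d <- cpp_fraction_dose(pts, cp$angle * pi / 180, cp$couch_z, cp$weight,
                         leaf_cp, beam,
                         mv$voxels, mv_org, mv_sp, cal_mv$offset,
                         cal_mv$slope,
                         use_kv, kv_vox, kv_org, kv_sp, kco, kcs)
  arr <- array(d, dim = c(length(grid$y), length(grid$x), length(grid$z)))
  dose_cube(arr, origin = c(grid$x[1], grid$y[1]),
            pixel_spacing = c(grid$spacing[2], grid$spacing[1]),
            slice_positions = grid$z,
            downsample_factor = grid$factor,
            frame_of_reference = mv$frame_of_reference)
}

#' 3%/3 mm box-index agreement between two dose cubes
#'
#' A point passes when some reference voxel within the distance box holds a
#' dose within `dose_tol` (fraction of the reference maximum) of the
#' evaluated dose.  Points shallower than `min_depth` inside the body are
#' excluded, as are points outside the body.
#'
#' @param ref,eval [dose_cube()]s on the same grid.
#' @param dose_tol dose tolerance as a fraction of the reference maximum
#'   (default 0.03).
#' @param dist_tol box half-width, mm (default 3).
#' @param min_depth minimum depth inside the body, mm (default 5).
#' @param body_mask logical array on the grid marking the patient; `NULL`
#'   evaluates every point.
#' @return list with `pass_fraction`, `n_eval`, `n_pass`.
#' @export
box_index <- function(ref, eval, dose_tol = 0.03, dist_tol = 3,
                      min_depth = 5, body_mask = NULL) {
  if (!all(dim(ref$dose) == dim(eval$dose)))
    stop("dose cubes must share a grid")
  d <- dim(ref$dose)
  if (is.null(body_mask)) {
    eligible <- array(TRUE, d)
  } else {
    eligible <- erode_mask(body_mask,
                           c(ref$pixel_spacing[1], ref$pixel_spacing[2],
                             slice_spacing(ref)), min_depth)
  }
  if (!any(eligible)) stop("no evaluable points (empty eligible set)")
  tol_abs <- dose_tol * max(ref$dose)
  res <- cpp_box_index(ref$dose, eval$dose,
                       c(ref$pixel_spacing[2], ref$pixel_spacing[1],
                         slice_spacing(ref)),
                       tol_abs, dist_tol, as.logical(eligible))
  list(pass_fraction = res$n_pass / res$n_eval,
       n_eval = res$n_eval, n_pass = res$n_pass)
}

#' Dose at arbitrary points
#'
#' Bilinear in-plane interpolation on the nearest dose plane (the SI grid
#' is the coarse 6-mm slice lattice, so no interpolation is done along z).
#'
#' @param cube a [dose_cube()].
#' @param pts n x 3 matrix of (x, y, z) mm.
#' @return dose in Gy at each point.
#' @export
dose_at_points <- function(cube, pts) {
  pts <- rbind(pts)
  xs <- vol_x(cube); ys <- vol_y(cube)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    s <- which.min(abs(cube$slice_positions - pts[i, 3]))
    out[i] <- cpp_bilinear(cube$dose[, , s],
                           (pts[i, 2] - ys[1]) / cube$pixel_spacing[1],
                           (pts[i, 1] - xs[1]) / cube$pixel_spacing[2], 0)
  }
  out
}

# binary erosion of a 3D mask by a physical depth (separate in-plane /
# through-plane radii, box structuring element)
erode_mask <- function(mask, spacing_rcz, depth_mm) {
  d <- dim(mask)
  rr <- floor(depth_mm / spacing_rcz[1])
  rc <- floor(depth_mm / spacing_rcz[2])
  rz <- floor(depth_mm / spacing_rcz[3])
  out <- mask
  for (s in seq_len(d[3])) {
    if (s - rz < 1 || s + rz > d[3]) { out[, , s] <- FALSE; next }
    sl <- apply(mask[, , (s - rz):(s + rz), drop = FALSE], c(1, 2), all)
    # in-plane erosion by shifting
    acc <- sl
    for (i in -rr:rr) for (j in -rc:rc) {
      sh <- shift_mat(sl, i, j, FALSE)
      acc <- acc & sh
    }
    out[, , s] <- acc
  }
  out
}

shift_mat <- function(m, di, dj, fill) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  ri <- seq_len(d[1]) - di; ci <- seq_len(d[2]) - dj
  ok_r <- ri >= 1 & ri <= d[1]; ok_c <- ci >= 1 & ci <= d[2]
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}
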