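# Composite kV/MV radiological path length.  The MV scan circle is too
# small to cover the whole patient, so the kV image is masked to zero
# density inside the circle, aligned onto the MV frame using the recorded
# shifts and roll, and the water-equivalent path length (WEPL) of a ray is
# the sum of two Siddon traces -- one through each image.  No composite
# image is ever built.

#' MV scan circle
#'
#' @param center in-plane (x, y) centre in mm, isocentre-referenced.
#' @param diameter circle diameter in mm; the MV CT field of view is
#'   38.6 cm.
#' @return object of class `scan_circle`.
#' @export
scan_circle <- function(center = c(0, 0), diameter = 386) {
  if (diameter < 0) stop("diameter must be non-negative")
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "scan_circle")
}

#' Mask a kV image to zero density inside the MV scan circle
#'
#' Voxels whose in-plane centre lies strictly inside the circle are set to
#' -1000 HU (zero density); boundary voxels are left unmasked.  The circle
#' must be expressed in the aligned (MV) frame, so masking follows
#' [align_kv()].
#'
#' @param vol an [image_volume()] (normally the aligned kV volume).
#' @param circle a [scan_circle()].
#' @return the masked [image_volume()].
#' @export
mask_scan_circle <- function(vol, circle) {
  r2 <- (circle$diameter / 2)^2
  if (r2 == 0) return(vol)
  xs <- vol_x(vol) - circle$center[1]
  ys <- vol_y(vol) - circle$center[2]
  inside <- outer(ys, xs, function(dy, dx) dx^2 + dy^2 < r2)
  for (s in seq_len(dim(vol$voxels)[3])) {
    sl <- vol$voxels[, , s]
    sl[inside] <- -1000
    vol$voxels[, , s] <- sl
  }
  vol
}

#' Align the kV volume onto the MV frame
#'
#' Applies the in-plane translation (dx, dy) and a rotation by `-roll`
#' about the isocentre axis (the compensation for the roll applied at
#' treatment), resampling each slice with bilinear interpolation and a
#' -1000 HU fill outside the original field.  The superior-inferior shift
#' dz is applied by shifting the slice coordinates; no resampling is done
#' along z.
#'
#' @param vol the kV [image_volume()].
#' @param reg a [registration()]; must be usable.
#' @param isocentre in-plane (x, y) isocentre, mm.
#' @return the aligned [image_volume()].
#' @export
align_kv <- function(vol, reg, isocentre = c(0, 0)) {
  if (!reg$usable) stop("registration flagged unusable; fraction skipped")
  d <- dim(vol$voxels)
  xs <- vol_x(vol); ys <- vol_y(vol)
  # output voxel at (x, y) takes its value from the inverse-transformed
  # source position: undo translation, then rotate by +roll about the iso
  g <- expand.grid(y = ys, x = xs)
  src <- rot2(cbind(g$x - reg$dx, g$y - reg$dy), reg$roll, isocentre)
  col_idx <- (src[, 1] - vol$origin[1]) / vol$pixel_spacing[2]
  row_idx <- (src[, 2] - vol$origin[2]) / vol$pixel_spacing[1]
  out <- vol$voxels
  for (s in seq_len(d[3])) {
    v <- cpp_bilinear(vol$voxels[, , s], row_idx, col_idx, -1000)
    out[, , s] <- matrix(v, nrow = d[1], ncol = d[2])
  }
  vol$voxels <- out
  vol$slice_positions <- vol$slice_positions + reg$dz
  vol$origin <- vol$origin   # in-plane grid unchanged; values were resampled
  vol
}

#' Water-equivalent path length of a ray through one volume
#'
#' Integrates relative electron density along the segment from `p0` to `p1`
#' by exact voxel-boundary (Siddon-style) traversal, treating voxel values
#' as piecewise constant.  Segments outside the volume contribute zero.
#'
#' @param p0,p1 length-3 (x, y, z) mm endpoints, or n x 3 matrices for many
#'   rays.
#' @param vol an [image_volume()].
#' @param line the [calibration_line()] valid for the volume's modality and
#'   date.
#' @return list with `length` (geometric mm) and `wepl` (mm); vectors when
#'   matrices were supplied.
#' @export
trace_wepl <- function(p0, p1, vol, line) {
  p0 <- rbind(p0); p1 <- rbind(p1)
  sp <- c(vol$pixel_spacing[2], vol$pixel_spacing[1], slice_spacing(vol))
  org <- c(vol$origin[1], vol$origin[2], vol$slice_positions[1])
  w <- cpp_wepl(vol$voxels, org, sp, p0, p1, line$offset, line$slope)
  list(length = as.numeric(sqrt(rowSums((p1 - p0)^2))),
       wepl = as.numeric(w))
}

#' Composite WEPL through the MV image and the masked kV image
#'
#' The radiological path length to a point is the sum of the traces through
#' the MV image and through the masked, aligned kV image.
#'
#' @param p0,p1 ray endpoints (mm), vectors or n x 3 matrices.
#' @param mv the MV [image_volume()].
#' @param masked_kv the kV volume already aligned to the MV frame and
#'   masked with [mask_scan_circle()]; may be `NULL` for a single-image
#'   trace.
#' @param cal_mv,cal_kv [calibration_line()]s for the two images.
#' @return WEPL in mm (numeric vector).
#' @export
dual_wepl <- function(p0, p1, mv, masked_kv, cal_mv, cal_kv = kv_calibration()) {
  w <- trace_wepl(p0, p1, mv, cal_mv)$wepl
  if (!is.null(masked_kv))
    w <- w + trace_wepl(p0, p1, masked_kv, cal_kv)$wepl
  w
}

#' Dose-grid points derived from an MV image
#'
#' In-plane spacing is the MV pixel spacing times a power-of-two
#' downsampling factor; there is one plane per MV slice, so the SI spacing
#' is the MV slice interval (6 mm for coarse acquisitions).
#'
#' @param vol the MV [image_volume()].
#' @param factor in-plane downsampling factor (1, 2, 4, 8, ...).
#' @return list with `x`, `y` (in-plane coordinate vectors, mm), `z` (slice
#'   positions), `spacing` (x, y mm pair) and `factor`.
#' @export
make_dose_grid <- function(vol, factor = 2) {
  if (!is_pow2(factor)) stop("downsampling factor must be a power of 2")
  factor <- as.integer(factor)
  d <- dim(vol$voxels)
  list(x = vol_x(vol)[seq(1, d[2], by = factor)],
       y = vol_y(vol)[seq(1, d[1], by = factor)],
       z = vol$slice_positions,
       spacing = vol$pixel_spacing[c(2, 1)] * factor,
       factor = factor)
}
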