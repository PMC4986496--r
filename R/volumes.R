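#' @useDynLib voxcalc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CT image volume
#'
#' Container for a CT image stack in Hounsfield units with its geometry.
#' Voxels are stored as an array `[row, col, slice]`; x runs along columns
#' (patient left positive), y along rows (posterior positive), z along slices
#' (superior positive) -- the DICOM LPS convention.  The voxel value is
#' located at the voxel centre and voxel `[1, 1, 1]` is centred at `origin`.
#' HU below -1000 are clamped on construction because -1000 corresponds to
#' zero density in the masking and calibration model.
#'
#' @param voxels numeric array `[row, col, slice]` of HU.
#' @param origin length-2 (x, y) mm position of the first voxel centre;
#'   the z coordinate comes from `slice_positions`.
#' @param pixel_spacing length-2 (row, col) in-plane spacing, mm.
#' @param slice_positions strictly increasing z positions, mm.
#' @param modality `"kV"` or `"MV"`.
#' @param acquisition_date a `Date`.
#' @param machine_id machine identifier string.
#' @param frame_of_reference frame-of-reference identifier.
#' @param private named list of private header values (shift/roll tags).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, origin, pixel_spacing, slice_positions,
                         modality = c("kV", "MV"),
                         acquisition_date = Sys.Date(),
                         machine_id = "A",
                         frame_of_reference = "FOR.1",
                         private = list()) {
  modality <- match.arg(modality)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L,
            length(origin) == 2L, length(pixel_spacing) == 2L,
            all(pixel_spacing > 0),
            length(slice_positions) == dim(voxels)[3L])
  if (length(slice_positions) > 1L && any(diff(slice_positions) <= 0))
    stop("slice_positions must be strictly increasing")
  voxels[voxels < -1000] <- -1000
  structure(list(voxels = voxels,
                 origin = as.numeric(origin),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_positions = as.numeric(slice_positions),
                 modality = modality,
                 acquisition_date = as.Date(acquisition_date),
                 machine_id = machine_id,
                 frame_of_reference = frame_of_reference,
                 private = private),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d  spacing %.3g x %.3g mm, %d slices\n",
              x$modality, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2], d[3]))
  cat(sprintf("  origin (%.2f, %.2f) mm, z %.2f..%.2f mm, machine %s, %s\n",
              x$origin[1], x$origin[2], min(x$slice_positions),
              max(x$slice_positions), x$machine_id,
              format(x$acquisition_date)))
  invisible(x)
}

#' Per-fraction registration record
#'
#' Couch shifts (mm) and roll (degrees) applied at treatment, plus a usable
#' flag; images tagged not-to-be-used get `usable = FALSE`.
#'
#' @param dx,dy,dz shifts in mm (x = left, y = posterior, z = superior).
#' @param roll roll in degrees; rejected beyond `max_roll`.
#' @param usable logical.
#' @param max_roll sanity bound on `|roll|`, degrees.
#' @return object of class `registration`.
#' @export
registration <- function(dx = 0, dy = 0, dz = 0, roll = 0, usable = TRUE,
                         max_roll = 10) {
  vals <- c(dx, dy, dz, roll)
  if (any(!is.finite(vals))) stop("registration values must be finite")
  if (abs(roll) >= max_roll)
    stop(sprintf("|roll| = %.2f deg exceeds the %.1f deg sanity bound",
                 abs(roll), max_roll))
  structure(list(dx = dx, dy = dy, dz = dz, roll = roll,
                 usable = isTRUE(usable)),
            class = "registration")
}

#' Planar contour set
#'
#' A set of closed planar polygons in absolute mm patient coordinates, each
#' attached to a slice z position.  Polygons are implicitly closed (the last
#' vertex is not a duplicate of the first) and must be simple with at least
#' three vertices.
#'
#' @param contours list of `list(z = <mm>, vertices = <n x 2 matrix>)`.
#' @param structure_name structure name, e.g. `"Rectum"`.
#' @param frame_of_reference frame-of-reference identifier.
#' @return object of class `contour_set`.
#' @export
contour_set <- function(contours, structure_name = "Rectum",
                        frame_of_reference = "FOR.1") {
  for (ct in contours) {
    v <- ct$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      stop("each contour needs a vertex matrix with >= 3 rows and 2 columns")
    if (isTRUE(all.equal(v[1L, ], v[nrow(v), ])))
      stop("contours are implicitly closed; do not duplicate the first vertex")
  }
  zs <- vapply(contours, function(ct) ct$z, numeric(1))
  structure(list(contours = contours[order(zs)],
                 structure_name = structure_name,
                 frame_of_reference = frame_of_reference),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  zs <- contour_zs(x)
  cat(sprintf("<contour_set> '%s': %d contours, z %.1f..%.1f mm\n",
              x$structure_name, length(x$contours),
              if (length(zs)) min(zs) else NA, if (length(zs)) max(zs) else NA))
  invisible(x)
}

#' Slice z positions of a contour set
#' @param cs a `contour_set`.
#' @return numeric vector of z positions (mm), sorted.
#' @export
contour_zs <- function(cs) vapply(cs$contours, function(ct) ct$z, numeric(1))

#' Dose cube
#'
#' Dose in Gy on a grid derived from an MV image; shares the `image_volume`
#' geometry conventions plus a power-of-two in-plane downsampling factor.
#'
#' @param dose numeric array `[row, col, slice]`, Gy, all `>= 0`.
#' @param origin,pixel_spacing,slice_positions,frame_of_reference as for
#'   [image_volume()]; `pixel_spacing` is the (already downsampled) grid
#'   spacing.
#' @param downsample_factor integer power of 2.
#' @return object of class `dose_cube`.
#' @export
dose_cube <- function(dose, origin, pixel_spacing, slice_positions,
                      downsample_factor = 1L,
                      frame_of_reference = "FOR.1") {
  dose <- as.array(dose)
  if (length(dim(dose)) == 2L) dim(dose) <- c(dim(dose), 1L)
  if (length(dim(dose)) != 3L) stop("dose must be a 3-d array")
  if (any(dose < 0)) stop("dose must be non-negative")
  if (!is_pow2(downsample_factor))
    stop("downsample_factor must be a power of 2")
  structure(list(dose = dose,
                 origin = as.numeric(origin),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_positions = as.numeric(slice_positions),
                 downsample_factor = as.integer(downsample_factor),
                 frame_of_reference = frame_of_reference),
            class = "dose_cube")
}

is_pow2 <- function(n) {
  n <- as.numeric(n)
  length(n) == 1L && n >= 1 && abs(log2(n) - round(log2(n))) < 1e-9
}

# in-plane voxel-centre coordinate vectors of a volume/cube
vol_x <- function(v) v$origin[1] + (seq_len(dim_of(v)[2]) - 1) * v$pixel_spacing[2]
vol_y <- function(v) v$origin[2] + (seq_len(dim_of(v)[1]) - 1) * v$pixel_spacing[1]

dim_of <- function(v) dim(if (!is.null(v$voxels)) v$voxels else v$dose)

# uniform slice spacing (errors if the stack is non-uniform beyond tolerance)
slice_spacing <- function(v) {
  z <- v$slice_positions
  if (length(z) == 1L) return(1)
  dz <- diff(z)
  if (max(dz) - min(dz) > 1e-6 * max(abs(dz)) + 1e-9)
    stop("slice positions are not uniformly spaced")
  dz[1]
}

# rotate points (n x 2) by theta degrees about a centre, in LPS (x, y)
rot2 <- function(p, theta_deg, centre = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(p, 2, centre) %*% t(R), 2, centre, `+`)
}

# polygon area (shoelace, absolute) and centroid
poly_area <- function(v) abs(pracma::polyarea(v[, 1], v[, 2]))

poly_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# cumulative arc length of the closed polygon (returns per-vertex s and total)
poly_arclength <- function(v) {
  vc <- rbind(v, v[1L, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  list(s = c(0, cumsum(seg))[seq_len(nrow(v))], total = sum(seg))
}
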