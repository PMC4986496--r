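# DICOM-convention I/O for CT series, registration tags, RTSTRUCT contour
# sets and RTDOSE cubes.  The shift/roll record travels in a private block
# (group 0x0071, creator "VOXCALC"): 0x1001..0x1004 = dx, dy, dz, roll;
# 0x1005 = "N" marks an image not to be used for recalculation (absent means
# usable); 0x1010 carries the dose-cube downsampling factor.

SOP_CT      <- "1.2.840.10008.5.1.4.1.1.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
PRIV_GROUP  <- 0x0071

#' Write a CT image volume as a DICOM series (one file per slice)
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param reg optional [registration()]; when given, shift/roll private tags
#'   are added to every slice header (the MV-series convention).
#' @return the directory, invisibly.
#' @export
write_ct_series <- function(vol, dir, reg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$voxels)
  series_uid <- dcm_uid()
  for (s in seq_len(d[3])) {
    px <- as.integer(round(t(vol$voxels[, , s])))   # row-major pixel order
    els <- list(
      dcm_el(0x0008, 0x0016, "UI", SOP_CT),
      dcm_el(0x0008, 0x0018, "UI", paste0(series_uid, ".", s)),
      dcm_el(0x0008, 0x0022, "DA", format(vol$acquisition_date, "%Y%m%d")),
      dcm_el(0x0008, 0x0060, "CS", "CT"),
      dcm_el(0x0008, 0x103E, "LO", paste0(vol$modality, "CT")),
      dcm_el(0x0008, 0x1010, "SH", vol$machine_id),
      dcm_el(0x0020, 0x000E, "UI", series_uid),
      dcm_el(0x0020, 0x0032, "DS", c(vol$origin, vol$slice_positions[s])),
      dcm_el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
      dcm_el(0x0020, 0x0052, "UI", vol$frame_of_reference),
      dcm_el(0x0028, 0x0002, "US", 1L),
      dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_el(0x0028, 0x0010, "US", d[1]),
      dcm_el(0x0028, 0x0011, "US", d[2]),
      dcm_el(0x0028, 0x0030, "DS", vol$pixel_spacing),
      dcm_el(0x0028, 0x0100, "US", 16L),
      dcm_el(0x0028, 0x0101, "US", 16L),
      dcm_el(0x0028, 0x0102, "US", 15L),
      dcm_el(0x0028, 0x0103, "US", 1L),
      dcm_el(0x0028, 0x1052, "DS", 0),
      dcm_el(0x0028, 0x1053, "DS", 1),
      dcm_el(0x7FE0, 0x0010, "OW", px))
    if (!is.null(reg)) {
      els <- c(els, list(
        dcm_el(PRIV_GROUP, 0x0010, "LO", "VOXCALC"),
        dcm_el(PRIV_GROUP, 0x1001, "DS", reg$dx),
        dcm_el(PRIV_GROUP, 0x1002, "DS", reg$dy),
        dcm_el(PRIV_GROUP, 0x1003, "DS", reg$dz),
        dcm_el(PRIV_GROUP, 0x1004, "DS", reg$roll)))
      if (!reg$usable)
        els <- c(els, list(dcm_el(PRIV_GROUP, 0x1005, "CS", "N")))
    }
    dcm_write(els, file.path(dir, sprintf("ct_%03d.dcm", s)),
              sop_class = SOP_CT)
  }
  invisible(dir)
}

#' Read a DICOM CT series from a directory
#'
#' Slices are sorted by z position regardless of file order; the rescale
#' slope/intercept is applied to produce HU.  Mixed frames of reference,
#' non-uniform in-plane spacing across slices, or a slice missing its
#' position attribute are rejected.
#'
#' @param dir directory containing one DICOM file per slice.
#' @return an [image_volume()]; private shift/roll tag values appear in
#'   `$private`.
#' @export
read_ct_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM files in ", dir)
  slices <- lapply(files, function(f) {
    e <- dcm_read(f)
    pos <- dcm_get(e, 0x0020, 0x0032)
    if (is.null(pos) || length(pos) != 3)
      stop("slice missing image position attribute: ", f)
    list(e = e, pos = pos, f = f)
  })
  fors <- vapply(slices, function(s) {
    v <- dcm_get(s$e, 0x0020, 0x0052); if (is.null(v)) "" else v
  }, character(1))
  if (length(unique(fors)) != 1L)
    stop("mixed frames of reference in ", dir)
  sp <- lapply(slices, function(s) dcm_get(s$e, 0x0028, 0x0030))
  if (max(vapply(sp, function(p) max(abs(p - sp[[1]])), numeric(1))) > 1e-6)
    stop("non-uniform in-plane spacing across slices in ", dir)
  zs <- vapply(slices, function(s) s$pos[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (any(diff(zs) <= 0)) stop("duplicate slice positions in ", dir)

  e1 <- slices[[1]]$e
  nr <- dcm_get(e1, 0x0028, 0x0010)
  nc <- dcm_get(e1, 0x0028, 0x0011)
  vox <- array(0, dim = c(nr, nc, length(slices)))
  for (s in seq_along(slices)) {
    e <- slices[[s]]$e
    px <- dcm_get(e, 0x7FE0, 0x0010)
    slope <- dcm_get(e, 0x0028, 0x1053); if (is.null(slope)) slope <- 1
    inter <- dcm_get(e, 0x0028, 0x1052); if (is.null(inter)) inter <- 0
    vox[, , s] <- t(matrix(px * slope + inter, nrow = nc, ncol = nr))
  }
  desc <- dcm_get(e1, 0x0008, 0x103E)
  modality <- if (!is.null(desc) && startsWith(desc, "MV")) "MV" else "kV"
  da <- dcm_get(e1, 0x0008, 0x0022)
  machine <- dcm_get(e1, 0x0008, 0x1010)
  priv <- list()
  priv$dx <- dcm_get(e1, PRIV_GROUP, 0x1001)
  priv$dy <- dcm_get(e1, PRIV_GROUP, 0x1002)
  priv$dz <- dcm_get(e1, PRIV_GROUP, 0x1003)
  priv$roll <- dcm_get(e1, PRIV_GROUP, 0x1004)
  priv$skip <- dcm_get(e1, PRIV_GROUP, 0x1005)
  priv$source <- dir
  image_volume(vox,
               origin = slices[[1]]$pos[1:2],
               pixel_spacing = sp[[1]],
               slice_positions = zs,
               modality = modality,
               acquisition_date = if (is.null(da)) Sys.Date() else
                 as.Date(da, format = "%Y%m%d"),
               machine_id = if (is.null(machine)) "unknown" else machine,
               frame_of_reference = fors[1],
               private = priv)
}

#' Extract the registration record from MV series metadata
#'
#' Shifts are read from the private header block.  A missing roll tag yields
#' roll 0 with a warning; missing shift tags are an error naming the
#' fraction.  The usable flag is `FALSE` only when the skip tag is present
#' (the tag is written only to mark exclusions).
#'
#' @param vol an [image_volume()] read with [read_ct_series()].
#' @return a [registration()].
#' @export
read_registration <- function(vol) {
  p <- vol$private
  id <- if (!is.null(p$source)) p$source else
    paste(vol$machine_id, format(vol$acquisition_date))
  if (is.null(p$dx) || is.null(p$dy) || is.null(p$dz))
    stop("missing shift tags for fraction: ", id)
  roll <- p$roll
  if (is.null(roll)) {
    warning("roll tag absent for fraction ", id, "; assuming roll = 0")
    roll <- 0
  }
  registration(dx = p$dx, dy = p$dy, dz = p$dz, roll = roll,
               usable = is.null(p$skip) || !identical(p$skip, "N"))
}

#' Write / read a dose cube as a DICOM RTDOSE object
#'
#' Dose is stored as 16-bit unsigned integers with a dose-grid-scaling
#' factor, so the round-trip error is bounded by half the scaling quantum.
#'
#' @param cube a [dose_cube()].
#' @param path output file.
#' @return `write_dose`: the path, invisibly; `read_dose`: a [dose_cube()].
#' @export
write_dose <- function(cube, path) {
  if (any(cube$dose < 0)) stop("negative dose cannot be encoded")
  d <- dim(cube$dose)
  mx <- max(cube$dose)
  scaling <- if (mx > 0) mx / 65535 else 1
  px <- integer(0)
  for (s in seq_len(d[3]))
    px <- c(px, as.integer(round(t(cube$dose[, , s]) / scaling)))
  dz <- cube$slice_positions - cube$slice_positions[1]
  els <- list(
    dcm_el(0x0008, 0x0016, "UI", SOP_RTDOSE),
    dcm_el(0x0008, 0x0018, "UI", dcm_uid()),
    dcm_el(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_el(0x0020, 0x0032, "DS", c(cube$origin, cube$slice_positions[1])),
    dcm_el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    dcm_el(0x0020, 0x0052, "UI", cube$frame_of_reference),
    dcm_el(0x0028, 0x0002, "US", 1L),
    dcm_el(0x0028, 0x0008, "IS", d[3]),
    dcm_el(0x0028, 0x0010, "US", d[1]),
    dcm_el(0x0028, 0x0011, "US", d[2]),
    dcm_el(0x0028, 0x0030, "DS", cube$pixel_spacing),
    dcm_el(0x0028, 0x0100, "US", 16L),
    dcm_el(0x0028, 0x0101, "US", 16L),
    dcm_el(0x0028, 0x0102, "US", 15L),
    dcm_el(0x0028, 0x0103, "US", 0L),
    dcm_el(0x3004, 0x0002, "CS", "GY"),
    dcm_el(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_el(0x3004, 0x000A, "CS", "FRACTION"),
    dcm_el(0x3004, 0x000C, "DS", dz),
    dcm_el(0x3004, 0x000E, "DS", scaling),
    dcm_el(PRIV_GROUP, 0x0010, "LO", "VOXCALC"),
    dcm_el(PRIV_GROUP, 0x1010, "IS", cube$downsample_factor),
    dcm_el(0x7FE0, 0x0010, "OW", px))
  dcm_write(els, path, sop_class = SOP_RTDOSE)
  invisible(path)
}

#' @rdname write_dose
#' @export
read_dose <- function(path) {
  e <- dcm_read(path)
  nr <- dcm_get(e, 0x0028, 0x0010)
  nc <- dcm_get(e, 0x0028, 0x0011)
  nf <- dcm_get(e, 0x0028, 0x0008)
  scaling <- dcm_get(e, 0x3004, 0x000E)
  px <- dcm_get(e, 0x7FE0, 0x0010)
  px[px < 0] <- px[px < 0] + 65536   # stored unsigned
  pos <- dcm_get(e, 0x0020, 0x0032)
  dzv <- dcm_get(e, 0x3004, 0x000C)
  dsf <- dcm_get(e, PRIV_GROUP, 0x1010); if (is.null(dsf)) dsf <- 1L
  dose <- array(0, dim = c(nr, nc, nf))
  for (s in seq_len(nf)) {
    from <- (s - 1L) * nr * nc
    dose[, , s] <- t(matrix(px[from + seq_len(nr * nc)], nrow = nc))
  }
  fr <- dcm_get(e, 0x0020, 0x0052)
  dose_cube(dose * scaling, origin = pos[1:2],
            pixel_spacing = dcm_get(e, 0x0028, 0x0030),
            slice_positions = pos[3] + dzv,
            downsample_factor = dsf,
            frame_of_reference = if (is.null(fr)) "FOR.1" else fr)
}

#' Write / read a contour set as a DICOM RT structure set
#'
#' @param cs a [contour_set()]; open polylines (fewer than 3 vertices) are
#'   rejected by the container itself.
#' @param path output file.
#' @return `write_structure_set`: the path, invisibly;
#'   `read_structure_set`: a [contour_set()].
#' @export
write_structure_set <- function(cs, path) {
  contour_items <- lapply(cs$contours, function(ct) {
    xyz <- as.numeric(t(cbind(ct$vertices, ct$z)))
    list(dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
         dcm_el(0x3006, 0x0046, "IS", nrow(ct$vertices)),
         dcm_el(0x3006, 0x0050, "DS", xyz))
  })
  els <- list(
    dcm_el(0x0008, 0x0016, "UI", SOP_RTSTRUCT),
    dcm_el(0x0008, 0x0018, "UI", dcm_uid()),
    dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x3006, 0x0020, "SQ", list(list(
      dcm_el(0x3006, 0x0022, "IS", 1L),
      dcm_el(0x3006, 0x0024, "UI", cs$frame_of_reference),
      dcm_el(0x3006, 0x0026, "LO", cs$structure_name)))),
    dcm_el(0x3006, 0x0039, "SQ", list(c(
      list(dcm_el(0x3006, 0x0040, "SQ", contour_items)),
      list(dcm_el(0x3006, 0x0084, "IS", 1L))))))
  dcm_write(els, path, sop_class = SOP_RTSTRUCT)
  invisible(path)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(path) {
  e <- dcm_read(path)
  roi <- dcm_get(e, 0x3006, 0x0020)[[1]]
  name <- dcm_get(roi, 0x3006, 0x0026)
  for_uid <- dcm_get(roi, 0x3006, 0x0024)
  rcs <- dcm_get(e, 0x3006, 0x0039)[[1]]
  citems <- dcm_get(rcs, 0x3006, 0x0040)
  contours <- lapply(citems, function(it) {
    xyz <- matrix(dcm_get(it, 0x3006, 0x0050), ncol = 3, byrow = TRUE)
    if (nrow(xyz) < 3) stop("contour with fewer than 3 vertices in ", path)
    list(z = xyz[1, 3], vertices = xyz[, 1:2, drop = FALSE])
  })
  contour_set(contours, structure_name = name, frame_of_reference = for_uid)
}
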