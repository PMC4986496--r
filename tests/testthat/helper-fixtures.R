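# Shared fixtures, built in code at test time.

# a small uniform-water MV volume (HU = offset of the calibration line)
water_volume <- function(hu = 8, n = 60, spacing = 2, slices = 10,
                         modality = "MV") {
  image_volume(array(hu, c(n, n, slices)),
               origin = c(-(n - 1) / 2 * spacing, -(n - 1) / 2 * spacing),
               pixel_spacing = c(spacing, spacing),
               slice_positions = (seq_len(slices) - (slices + 1) / 2) * 6,
               modality = modality,
               acquisition_date = as.Date("2013-06-01"))
}

# random heterogeneous volume for ray-tracing oracles
random_volume <- function(seed = 1, n = 40, spacing = 2, slices = 8) {
  set.seed(seed)
  image_volume(array(sample(-1000:1500, n * n * slices, TRUE),
                     c(n, n, slices)),
               origin = c(-(n - 1) / 2 * spacing, -(n - 1) / 2 * spacing),
               pixel_spacing = c(spacing, spacing),
               slice_positions = (seq_len(slices) - (slices + 1) / 2) * 6,
               modality = "MV",
               acquisition_date = as.Date("2013-06-01"))
}

mv_line <- function() calibration_line(8, 970, as.Date("2012-07-01"), "A")

regular_polygon <- function(r = 10, centre = c(0, 0), n = 48) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# fine-step numerical WEPL integration (independent quadrature oracle)
wepl_quadrature <- function(p0, p1, vol, line, step = 0.01) {
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(0)
  nstep <- max(1, ceiling(L / step))
  t <- (seq_len(nstep) - 0.5) / nstep
  pts <- outer(t, p1 - p0) + matrix(p0, nstep, 3, byrow = TRUE)
  d <- dim(vol$voxels)
  ix <- round((pts[, 1] - vol$origin[1]) / vol$pixel_spacing[2]) + 1
  iy <- round((pts[, 2] - vol$origin[2]) / vol$pixel_spacing[1]) + 1
  dz <- if (d[3] > 1) vol$slice_positions[2] - vol$slice_positions[1] else 6
  iz <- round((pts[, 3] - vol$slice_positions[1]) / dz) + 1
  ok <- ix >= 1 & ix <= d[2] & iy >= 1 & iy <= d[1] & iz >= 1 & iz <= d[3]
  hu <- rep(-1000, nstep)
  hu[ok] <- vol$voxels[cbind(iy[ok], ix[ok], iz[ok])]
  rho <- pmax(0, 1 + (hu - line$offset) / line$slope)
  rho[!ok] <- 0
  sum(rho) * L / nstep
}

# brute-force per-point box-index search (independent of the C++ path)
box_index_brute <- function(ref, eval, spacing, dose_tol, dist_mm,
                            eligible) {
  d <- dim(ref)
  rr <- floor(dist_mm / spacing[1]); rc <- floor(dist_mm / spacing[2])
  rz <- floor(dist_mm / spacing[3])
  tol <- dose_tol * max(ref)
  n_eval <- 0; n_pass <- 0
  for (s in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!eligible[i, j, s]) next
    n_eval <- n_eval + 1
    nb <- ref[max(1, i - rr):min(d[1], i + rr),
              max(1, j - rc):min(d[2], j + rc),
              max(1, s - rz):min(d[3], s + rz)]
    if (any(abs(nb - eval[i, j, s]) <= tol)) n_pass <- n_pass + 1
  }
  list(pass_fraction = n_pass / n_eval, n_eval = n_eval, n_pass = n_pass)
}

# small pelvis spec for pipeline tests (compact geometry, study-default
# perturbations)
test_pelvis_spec <- function(seed = 7, n_fractions = 2, ...) {
  pelvis_spec(seed = seed, n_fractions = n_fractions, mv_size = 96,
              mv_spacing = 4, mv_slices = 6, kv_size = 112, kv_spacing = 4,
              kv_slices = 31, rectum_z_extent = c(-51, 51), ...)
}

scan_jaccard <- function(seg, fr) {
  m <- contours_to_mask(seg, fr$mv)
  zs <- contour_zs(seg)
  sl <- vapply(zs, function(z) which.min(abs(fr$mv$slice_positions - z)), 1L)
  conformity_index(m[, , sl, drop = FALSE], fr$truth[, , sl, drop = FALSE])
}
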