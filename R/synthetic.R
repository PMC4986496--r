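# Synthetic inputs: the density-insert cylindrical calibration phantom
# (with removable-plug configurations) and a pelvis phantom with a
# ground-truth rectum imaged over many fractions, plus a geometric helical
# plan generator.  Every generator is deterministic given its seed, and the
# ground-truth density maps are consistent with the HU images under the
# selected calibration line.

#' Cylindrical density-insert phantom specification
#'
#' A 300-mm water cylinder with two rings of removable plug holes (8 inner,
#' 12 outer).  `configuration` selects the plug state used in the
#' plug-removal experiment: `all_plugs` fills every hole with unit-density
#' plugs, `inner_removed` empties the inner ring, `all_removed` empties
#' every hole.  `insert_densities`, when given, assigns the calibration
#' insert densities to the first holes instead (for calibration studies).
#'
#' @param body_radius cylinder radius, mm.
#' @param inner_ring_radius,outer_ring_radius hole-centre ring radii, mm.
#' @param n_inner,n_outer holes per ring.
#' @param hole_radius plug radius, mm.
#' @param configuration plug state.
#' @param insert_densities optional densities for the first holes.
#' @param size in-plane image size (pixels).
#' @param spacing in-plane pixel spacing, mm.
#' @param n_slices,slice_spacing image extent along z.
#' @return a list of class `cheese_spec`.
#' @export
cheese_spec <- function(body_radius = 150, inner_ring_radius = 60,
                        outer_ring_radius = 105, n_inner = 8, n_outer = 12,
                        hole_radius = 12.5,
                        configuration = c("all_plugs", "inner_removed",
                                          "all_removed"),
                        insert_densities = NULL,
                        size = 128, spacing = 2.5, n_slices = 5,
                        slice_spacing = 6) {
  configuration <- match.arg(configuration)
  structure(as.list(environment()), class = "cheese_spec")
}

cheese_holes <- function(spec) {
  ang_i <- 2 * pi * (seq_len(spec$n_inner) - 1) / spec$n_inner
  ang_o <- 2 * pi * (seq_len(spec$n_outer) - 0.5) / spec$n_outer
  data.frame(x = c(spec$inner_ring_radius * cos(ang_i),
                   spec$outer_ring_radius * cos(ang_o)),
             y = c(spec$inner_ring_radius * sin(ang_i),
                   spec$outer_ring_radius * sin(ang_o)),
             ring = rep(c("inner", "outer"), c(spec$n_inner, spec$n_outer)),
             radius = spec$hole_radius)
}

#' Generate the density-insert phantom image
#'
#' HU values are synthesised from the ground-truth relative electron
#' densities through the forward calibration model; removed plugs become
#' air (density 0).
#'
#' @param spec a [cheese_spec()].
#' @param line the [calibration_line()] defining the forward model.
#' @param noise_sd Gaussian HU noise (0 = noise free).
#' @param modality,acquisition_date volume metadata.
#' @return list with `volume` (an [image_volume()]), `density` (the
#'   ground-truth density array) and `holes` (hole table with assigned
#'   densities).
#' @export
make_cheese_phantom <- function(spec, line, noise_sd = 0, modality = "MV",
                                acquisition_date = as.Date("2013-06-01")) {
  holes <- cheese_holes(spec)
  dmat <- as.matrix(stats::dist(holes[, c("x", "y")]))
  diag(dmat) <- Inf
  if (min(dmat) < 2 * spec$hole_radius) stop("overlapping inserts")
  holes$density <- 1
  if (!is.null(spec$insert_densities)) {
    k <- min(length(spec$insert_densities), nrow(holes))
    holes$density[seq_len(k)] <- spec$insert_densities[seq_len(k)]
  }
  removed <- switch(spec$configuration,
                    all_plugs = rep(FALSE, nrow(holes)),
                    inner_removed = holes$ring == "inner",
                    all_removed = rep(TRUE, nrow(holes)))
  holes$density[removed] <- 0

  half <- (spec$size - 1) / 2 * spec$spacing
  xs <- seq(-half, half, by = spec$spacing)
  ys <- xs
  den <- matrix(0, spec$size, spec$size)   # air outside the body
  rr2 <- outer(ys, xs, function(y, x) x^2 + y^2)
  den[rr2 < spec$body_radius^2] <- 1
  for (i in seq_len(nrow(holes))) {
    d2 <- outer(ys - holes$y[i], xs - holes$x[i],
                function(dy, dx) dx^2 + dy^2)
    den[d2 < spec$hole_radius^2] <- holes$density[i]
  }
  zs <- (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) *
    spec$slice_spacing
  den3 <- array(rep(den, spec$n_slices),
                dim = c(spec$size, spec$size, spec$n_slices))
  hu <- density_to_hu(den3, line)
  hu[den3 == 0] <- -1000
  if (noise_sd > 0) hu <- hu + stats::rnorm(length(hu), 0, noise_sd)
  vol <- image_volume(hu, origin = c(-half, -half),
                      pixel_spacing = c(spec$spacing, spec$spacing),
                      slice_positions = zs, modality = modality,
                      acquisition_date = acquisition_date,
                      machine_id = line$machine_id)
  list(volume = vol, density = den3, holes = holes)
}

#' Circular ROI specifications for the phantom inserts
#'
#' @param spec a [cheese_spec()].
#' @param shrink ROI radius as a fraction of the hole radius (avoids the
#'   partial-volume rim).
#' @return data frame usable with [measure_inserts()].
#' @export
cheese_roi_specs <- function(spec, shrink = 0.6) {
  holes <- cheese_holes(spec)
  holes$density <- 1
  if (!is.null(spec$insert_densities)) {
    k <- min(length(spec$insert_densities), nrow(holes))
    holes$density[seq_len(k)] <- spec$insert_densities[seq_len(k)]
  }
  data.frame(density = holes$density, x = holes$x, y = holes$y,
             radius = spec$hole_radius * shrink,
             slice = ceiling(spec$n_slices / 2))
}

#' Pelvis phantom specification
#'
#' An elliptical body (wider than the 386-mm MV scan circle, so the
#' composite kV/MV path is always exercised) containing muscle-equivalent
#' soft tissue, femoral heads, a prostate, and a rectum tube surrounded by
#' mesorectal fat.  Per fraction, the anatomy is displaced by random setup
#' shifts and roll, the rectum radius is jittered, and the daily image
#' degradations the segmentation corrections exist for are emulated:
#' sporadic gas pockets, occasional adjacent soft-tissue blobs that invite
#' contour leaks, and loss of fat contrast at the inferior end.
#'
#' @param seed RNG seed; the whole series is reproducible from it.
#' @param n_fractions number of daily fractions.
#' @param body_semi_axes (x, y) semi-axes of the body ellipse, mm.
#' @param body_hu,fat_hu,rectal_hu,prostate_hu,bone_hu tissue HU.
#' @param rectum_center in-plane rectum axis (x, y), mm.
#' @param rectum_radius nominal rectum radius, mm.
#' @param rectum_z_extent (min, max) SI extent of the rectum, mm.
#' @param fat_margin mesorectal fat thickness beyond the rectum radius, mm.
#' @param low_contrast_below below this z the fat contrast is absent and
#'   the rectal content approaches muscle HU (the inferior failure mode).
#' @param prostate_center,prostate_radius,prostate_z prostate sphere.
#' @param shift_sd,dz_sd,roll_sd per-fraction setup perturbation scales
#'   (mm, mm, degrees).
#' @param radius_jitter_sd per-fraction rectum radius jitter, mm.
#' @param gas_prob probability a fraction shows a gas pocket.
#' @param artifact_prob per-slice probability of a dark streak artifact.
#' @param mv_noise_sd,kv_noise_sd Gaussian HU noise.
#' @param mv_size,mv_spacing,mv_slices,mv_slice_spacing MV geometry
#'   (coarse 6-mm slices).
#' @param kv_size,kv_spacing,kv_slices,kv_slice_spacing kV geometry.
#' @param scan_circle_diameter MV field-of-view diameter, mm.
#' @param unusable_fractions indices flagged not-to-be-used.
#' @param fixed_registrations optional list of [registration()]s overriding
#'   the random setup draws (ground-truth transform tests).
#' @param machine_id,start_date volume metadata (the date selects the MV
#'   calibration line).
#' @return a list of class `pelvis_spec`.
#' @export
pelvis_spec <- function(seed = 1, n_fractions = 20,
                        body_semi_axes = c(200, 150),
                        body_hu = 40, fat_hu = -90, rectal_hu = 20,
                        prostate_hu = 45, bone_hu = 700,
                        rectum_center = c(0, 60), rectum_radius = 12,
                        rectum_z_extent = c(-57, 57), fat_margin = 22,
                        low_contrast_below = -18,
                        prostate_center = c(0, 20), prostate_radius = 22,
                        prostate_z = 8,
                        shift_sd = 3, dz_sd = 2, roll_sd = 0.5,
                        radius_jitter_sd = 1.5,
                        gas_prob = 0.25, artifact_prob = 0.12,
                        mv_noise_sd = 30, kv_noise_sd = 5,
                        mv_size = 160, mv_spacing = 2.4, mv_slices = 10,
                        mv_slice_spacing = 6,
                        kv_size = 180, kv_spacing = 2.4, kv_slices = 41,
                        kv_slice_spacing = 3,
                        scan_circle_diameter = 386,
                        unusable_fractions = integer(0),
                        fixed_registrations = NULL,
                        machine_id = "A",
                        start_date = as.Date("2013-06-01")) {
  structure(as.list(environment()), class = "pelvis_spec")
}

# baseline rectum radius profile (smooth taper along z)
.rectum_r0 <- function(spec, z) {
  spec$rectum_radius * (1 + 0.08 * sin(2 * pi * z / 120))
}

# render one slice of the pelvis at planning-space coordinates q (n x 2)
# and z; feat carries the fraction's deformation/features
.render_pelvis <- function(spec, qx, qy, z, feat) {
  hu <- rep(-1000, length(qx))
  a <- spec$body_semi_axes[1]; b <- spec$body_semi_axes[2]
  body <- (qx / a)^2 + (qy / b)^2 <= 1
  hu[body] <- spec$body_hu
  # femoral heads
  for (sx in c(-110, 110)) {
    d2 <- (qx - sx)^2 + (qy - 10)^2
    hu[body & d2 < 22^2 & abs(z) < 40] <- spec$bone_hu
  }
  # prostate sphere
  dz2 <- (z - spec$prostate_z)^2
  d2 <- (qx - spec$prostate_center[1])^2 + (qy - spec$prostate_center[2])^2
  hu[body & d2 + dz2 < spec$prostate_radius^2] <- spec$prostate_hu
  if (z >= spec$rectum_z_extent[1] && z <= spec$rectum_z_extent[2]) {
    rr <- feat$radius_fn(z)
    d2 <- (qx - spec$rectum_center[1])^2 + (qy - spec$rectum_center[2])^2
    if (z >= spec$low_contrast_below) {
      fat <- body & d2 < (rr + spec$fat_margin)^2 & d2 >= rr^2 &
        !(hu == spec$bone_hu)
      hu[fat] <- spec$fat_hu
      hu[body & d2 < rr^2] <- spec$rectal_hu
    } else {
      # inferior failure mode: the muscle complex around the low rectum is
      # indistinguishable from rectal content, so the only visible edge is
      # the fat boundary 12 mm beyond the true rectal wall -- the
      # overcontouring that fix_inferior exists to repair.  The true wall
      # stays at rr; only the image lacks the contrast to show it.
      blend <- rr + 12
      fat <- body & d2 < (blend + spec$fat_margin)^2 & d2 >= blend^2 &
        !(hu == spec$bone_hu)
      hu[fat] <- spec$fat_hu
      hu[body & d2 < blend^2] <- spec$rectal_hu
    }
    if (!is.null(feat$gas) && z >= feat$gas[1] && z <= feat$gas[2]) {
      gd2 <- (qx - spec$rectum_center[1])^2 +
        (qy - (spec$rectum_center[2] - rr * 0.35))^2
      hu[body & gd2 < (rr * 0.55)^2 & d2 < rr^2] <- -1000
    }
    # dark reconstruction streak crossing the rectum: a band of fat-like
    # HU at a random angle/offset, the single-slice failure the
    # smoothed-surface replacement exists to repair (image-only; the
    # anatomy underneath is intact)
    af <- feat$artifact[[as.character(round(z, 3))]]
    if (!is.null(af)) {
      nx_ <- cos(af[1]); ny_ <- sin(af[1])
      perp <- (qx - spec$rectum_center[1]) * nx_ +
        (qy - spec$rectum_center[2]) * ny_
      along2 <- (qx - spec$rectum_center[1])^2 +
        (qy - spec$rectum_center[2])^2
      hu[body & abs(perp - af[2]) < 3 & along2 < (rr + 25)^2] <- spec$fat_hu
    }
  }
  hu
}

.pelvis_truth <- function(spec, qx, qy, z, feat) {
  if (z < spec$rectum_z_extent[1] || z > spec$rectum_z_extent[2])
    return(rep(FALSE, length(qx)))
  rr <- feat$radius_fn(z)
  (qx - spec$rectum_center[1])^2 + (qy - spec$rectum_center[2])^2 < rr^2
}

#' Generate a full pelvis phantom series
#'
#' Returns the planning kV volume, the planning rectum contours, and one
#' MV volume + registration + ground-truth rectum mask per fraction.  The
#' fraction anatomy is the planning anatomy displaced by the drawn setup
#' shifts and roll (so applying the registration re-aligns it), with the
#' rectum radius jittered and the daily degradations added.  The same seed
#' reproduces the series bit for bit.
#'
#' @param spec a [pelvis_spec()].
#' @return list with `planning_kv`, `planning_contours`, `isocentre`, and
#'   `fractions` (each `list(mv, reg, truth)`).
#' @export
make_pelvis_series <- function(spec) {
  set.seed(spec$seed)
  iso <- c(0, 0)
  half_kv <- (spec$kv_size - 1) / 2 * spec$kv_spacing
  kx <- seq(-half_kv, half_kv, by = spec$kv_spacing)
  kz <- (seq_len(spec$kv_slices) - (spec$kv_slices + 1) / 2) *
    spec$kv_slice_spacing
  gk <- expand.grid(y = kx, x = kx)
  feat0 <- list(radius_fn = function(z) .rectum_r0(spec, z),
                gas = NULL, artifact = list())
  kvox <- array(0, c(spec$kv_size, spec$kv_size, spec$kv_slices))
  for (s in seq_along(kz))
    kvox[, , s] <- matrix(.render_pelvis(spec, gk$x, gk$y, kz[s], feat0),
                          spec$kv_size)
  if (spec$kv_noise_sd > 0)
    kvox <- kvox + stats::rnorm(length(kvox), 0, spec$kv_noise_sd)
  planning_kv <- image_volume(kvox, origin = c(-half_kv, -half_kv),
                              pixel_spacing = rep(spec$kv_spacing, 2),
                              slice_positions = kz, modality = "kV",
                              acquisition_date = spec$start_date - 14,
                              machine_id = spec$machine_id)
  # planning contours: circles of the baseline radius on each kV slice
  th <- 2 * pi * (seq_len(48) - 1) / 48
  pc <- list()
  for (z in kz) {
    if (z < spec$rectum_z_extent[1] || z > spec$rectum_z_extent[2]) next
    r0 <- .rectum_r0(spec, z)
    pc[[length(pc) + 1L]] <- list(z = z, vertices = cbind(
      spec$rectum_center[1] + r0 * cos(th),
      spec$rectum_center[2] + r0 * sin(th)))
  }
  planning_contours <- contour_set(pc, structure_name = "Rectum")

  half_mv <- (spec$mv_size - 1) / 2 * spec$mv_spacing
  mx <- seq(-half_mv, half_mv, by = spec$mv_spacing)
  mz <- (seq_len(spec$mv_slices) - (spec$mv_slices + 1) / 2) *
    spec$mv_slice_spacing
  gm <- expand.grid(y = mx, x = mx)
  circle_r2 <- (spec$scan_circle_diameter / 2)^2
  outside_circle <- gm$x^2 + gm$y^2 >= circle_r2

  fractions <- vector("list", spec$n_fractions)
  for (f in seq_len(spec$n_fractions)) {
    reg <- if (!is.null(spec$fixed_registrations)) {
      r <- spec$fixed_registrations[[f]]
      r$usable <- !(f %in% spec$unusable_fractions)
      r
    } else registration(dx = stats::rnorm(1, 0, spec$shift_sd),
                        dy = stats::rnorm(1, 0, spec$shift_sd),
                        dz = stats::rnorm(1, 0, spec$dz_sd),
                        roll = stats::rnorm(1, 0, spec$roll_sd),
                        usable = !(f %in% spec$unusable_fractions))
    aj <- stats::rnorm(1, 0, spec$radius_jitter_sd * 0.7)
    bj <- abs(stats::rnorm(1, 0, spec$radius_jitter_sd * 0.7))
    ph <- stats::runif(1, 0, 2 * pi)
    radius_fn <- local({
      aj <- aj; bj <- bj; ph <- ph
      function(z) pmax(6, .rectum_r0(spec, z) + aj +
                         bj * sin(2 * pi * z / 80 + ph))
    })
    gas <- NULL
    if (stats::runif(1) < spec$gas_prob) {
      g0 <- stats::runif(1, -20, 10)
      gas <- c(g0, g0 + stats::runif(1, 6, 14))
    }
    artifact <- list()
    for (s in seq_along(mz)) {
      zp <- mz[s] - reg$dz
      if (stats::runif(1) < spec$artifact_prob &&
          zp > spec$low_contrast_below + 6 &&
          zp >= spec$rectum_z_extent[1] && zp <= spec$rectum_z_extent[2]) {
        rr <- radius_fn(zp)
        # streak: angle of the band normal and perpendicular offset
        artifact[[as.character(round(zp, 3))]] <-
          c(stats::runif(1, 0, pi), stats::runif(1, -rr / 2, rr / 2))
      }
    }
    feat <- list(radius_fn = radius_fn, gas = gas, artifact = artifact)

    # fraction anatomy = T(planning), T = rot(-roll) then shift; render by
    # evaluating the planning scene at T^{-1}(voxel)
    src <- rot2(cbind(gm$x - reg$dx, gm$y - reg$dy), reg$roll, iso)
    mvox <- array(0, c(spec$mv_size, spec$mv_size, spec$mv_slices))
    truth <- array(FALSE, dim(mvox))
    for (s in seq_along(mz)) {
      zp <- mz[s] - reg$dz
      hu <- .render_pelvis(spec, src[, 1], src[, 2], zp, feat)
      hu[outside_circle] <- -1000
      mvox[, , s] <- matrix(hu, spec$mv_size)
      truth[, , s] <- matrix(.pelvis_truth(spec, src[, 1], src[, 2], zp,
                                           feat), spec$mv_size)
    }
    if (spec$mv_noise_sd > 0) {
      mvox <- mvox + stats::rnorm(length(mvox), 0, spec$mv_noise_sd)
      # no reconstruction signal outside the scan circle
      for (s in seq_along(mz)) {
        sl <- mvox[, , s]; sl[outside_circle] <- -1000; mvox[, , s] <- sl
      }
    }
    mv <- image_volume(mvox, origin = c(-half_mv, -half_mv),
                       pixel_spacing = rep(spec$mv_spacing, 2),
                       slice_positions = mz, modality = "MV",
                       acquisition_date = spec$start_date + f - 1,
                       machine_id = spec$machine_id)
    fractions[[f]] <- list(mv = mv, reg = reg, truth = truth)
  }
  list(planning_kv = planning_kv, planning_contours = planning_contours,
       isocentre = iso, fractions = fractions)
}

#' Geometric helical plan for a spherical target
#'
#' Leaf open-times are set by geometric coverage: a leaf is open in a
#' projection when its beamlet ray passes within the target radius of the
#' target centre, with linearly smoothed edges; an SI window with the same
#' smoothing keeps the fan on the target.
#'
#' @param target_center (x, y, z) target centre, mm.
#' @param target_radius target radius, mm.
#' @param n_rotations gantry rotations.
#' @param pitch couch travel per rotation, mm.
#' @param output_factor Gy per unit open-time (default gives a realistic
#'   2-3 Gy per fraction at the isocentre).
#' @param couch_start couch z at the first projection; by default the
#'   travel is centred on the target.
#' @param ... further arguments passed to [helical_plan()].
#' @return a [helical_plan()].
#' @export
make_prostate_plan <- function(target_center = c(0, 20, 8),
                               target_radius = 25, n_rotations = 5,
                               pitch = 15, output_factor = 0.05,
                               couch_start = NULL, ...) {
  plan0 <- helical_plan(matrix(0, 51 * n_rotations, 64), pitch = pitch,
                        output_factor = output_factor, ...)
  travel <- n_rotations * pitch
  plan0$couch_start <- if (is.null(couch_start))
    target_center[3] - travel / 2 else couch_start
  nproj <- nrow(plan0$leaf_open)
  lw <- plan0$leaf_width_at_iso
  leafc <- (seq_len(plan0$n_leaves) - (plan0$n_leaves + 1) / 2) * lw
  edge <- lw / 2
  open <- matrix(0, nproj, plan0$n_leaves)
  for (p in seq_len(nproj)) {
    ang <- (plan0$gantry_start +
              (p - 0.5) * 360 / plan0$projections_per_rotation) * pi / 180
    cz <- plan0$couch_start + (p - 0.5) * pitch /
      plan0$projections_per_rotation
    S <- plan0$isocentre + plan0$source_axis_distance * c(sin(ang), -cos(ang))
    u <- (plan0$isocentre - S) / plan0$source_axis_distance
    v <- c(-u[2], u[1])
    # lateral position of the target centre at the isocentre plane
    dt <- c(target_center[1], target_center[2]) - S
    depth <- sum(dt * u)
    if (depth <= 0) next    # target behind the source: beam cannot reach
    lat_t <- sum(dt * v) * plan0$source_axis_distance / depth
    zgate <- (target_radius + plan0$fan_extent / 2 + edge -
                abs(cz - target_center[3])) / (2 * edge)
    zgate <- min(1, max(0, zgate))
    if (zgate <= 0) next
    miss <- abs(leafc - lat_t)
    lateral <- pmin(1, pmax(0, (target_radius + edge - miss) / (2 * edge)))
    open[p, ] <- lateral * zgate
  }
  plan0$leaf_open <- open
  plan0
}
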