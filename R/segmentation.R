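# Rectum auto-segmentation on daily MV slices: a two-phase Chan-Vese level
# set seeded from the planning contour, followed by the three corrections
# used in practice -- air remapping during preprocessing, replacement of
# overcontoured inferior slices by planning contours, and replacement of
# outlier slices by a smoothed three-dimensional surface.

#' Segmentation parameters
#'
#' Defaults were tuned on the synthetic pelvis phantom; everything is
#' configurable.
#'
#' @param window_low,window_high HU rescale window; intensities are clipped
#'   here and mapped monotonically to `[0, 1]`.
#' @param air_threshold HU below which a pixel is treated as gas and
#'   remapped to `rectal_hu` before windowing.
#' @param rectal_hu HU of rectal material, the remap target for gas.
#' @param lambda1,lambda2 Chan-Vese region weights (inside / outside); the
#'   default outside weight compensates the inward bias a mixed background
#'   induces at coarse MV resolution (tuned on the synthetic phantom).
#' @param mu Chan-Vese boundary-length weight (on the `[0, 1]` rescaled
#'   image).
#' @param max_iter level-set iteration cap.
#' @param dt,delta_eps level-set time step and regularised-delta width
#'   (`delta_eps = 0` uses a global delta so weakly contrasted connected
#'   regions can switch phase).
#' @param presmooth_passes binomial-kernel smoothing passes applied to the
#'   image before the descent (noise conditioning; 0 disables).
#' @param inferior_area_ratio a slice is "unexpectedly large" when its area
#'   exceeds this multiple of the matching planning-contour area.
#' @param surface_dev_mm mean radial deviation (mm) from the smoothed
#'   surface beyond which a slice is replaced.
#' @param smooth_span number of slices in the moving polynomial fit.
#' @param n_rays radial rays used to resample contours about the centroid.
#' @param crop_margin mm margin around the planning contour defining the
#'   per-slice working region.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(window_low = -250, window_high = 250,
                       air_threshold = -300, rectal_hu = 20,
                       lambda1 = 1, lambda2 = 2, mu = 0.05,
                       max_iter = 300, dt = 4, delta_eps = 1,
                       presmooth_passes = 2,
                       inferior_area_ratio = 1.5, surface_dev_mm = 3,
                       smooth_span = 5, n_rays = 36, crop_margin = 18) {
  if (window_low >= window_high) stop("window_low must be < window_high")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(as.list(environment()), class = "seg_params")
}

#' Preprocess an MV slice for segmentation
#'
#' Gas pixels (below the air threshold) are reassigned the rectal-material
#' HU, then intensities are clipped to the window and mapped linearly to
#' `[0, 1]` (order-preserving inside the window).
#'
#' @param slice_hu numeric matrix of HU.
#' @param params a [seg_params()].
#' @return numeric matrix in `[0, 1]`.
#' @export
preprocess_slice <- function(slice_hu, params = seg_params()) {
  m <- slice_hu
  m[m < params$air_threshold] <- params$rectal_hu
  m <- pmin(pmax(m, params$window_low), params$window_high)
  (m - params$window_low) / (params$window_high - params$window_low)
}

#' Chan-Vese segmentation of one slice
#'
#' Minimises the two-phase piecewise-constant Chan-Vese energy (region
#' means c1/c2, boundary-length penalty `mu`) starting from the given
#' mask.  On a uniform image there is no gradient to follow and the init
#' mask is returned unchanged; if descent empties the foreground the init
#' mask is returned.
#'
#' @param image numeric matrix, normally from [preprocess_slice()].
#' @param init_mask logical matrix, non-empty.
#' @param params a [seg_params()].
#' @return logical matrix.
#' @export
chan_vese_slice <- function(image, init_mask, params = seg_params()) {
  if (!any(init_mask)) stop("init mask is empty")
  if (max(image) - min(image) < 1e-12) return(init_mask)
  for (k in seq_len(params$presmooth_passes)) image <- .blur121(image)
  m <- cpp_chan_vese(image, init_mask * 1L, params$mu, params$lambda1,
                     params$lambda2, params$max_iter, params$dt,
                     params$delta_eps)
  m > 0
}

# separable (1,2,1)/4 binomial blur with replicated edges
.blur121 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up <- m[c(1, seq_len(n - 1)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  m <- (up + 2 * m + dn) / 4
  lf <- m[, c(1, seq_len(p - 1)), drop = FALSE]
  rt <- m[, c(seq_len(p - 1) + 1, p), drop = FALSE]
  (lf + 2 * m + rt) / 4
}

# nearest positive intersection distance of the ray origin + t*dir with a
# polygon boundary; NA when the ray misses
poly_ray_intersect <- function(poly, origin, dir) {
  v <- rbind(poly, poly[1, ])
  best <- NA_real_
  for (i in seq_len(nrow(poly))) {
    a <- v[i, ]; b <- v[i + 1, ]
    e <- b - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a - origin
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    u <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9)
      if (is.na(best) || t < best) best <- t
  }
  best
}

#' Replace overcontoured inferior slices by planning contours
#'
#' The inferior rectum lacks the contrast to separate rectum from muscle,
#' which makes the level set overcontour there.  A slice is flagged when
#' its area exceeds `inferior_area_ratio` times the matching planning
#' area; all slices from the inferior end up to the most superior flagged
#' slice are replaced by the planning contours.  Slices superior to the
#' flagged slice are never altered.
#'
#' @param contours auto-segmented [contour_set()].
#' @param planning_contours planning [contour_set()] (already mapped into
#'   the same frame).
#' @param params a [seg_params()].
#' @return a [contour_set()] with attribute `replaced` (logical per slice).
#' @export
fix_inferior <- function(contours, planning_contours, params = seg_params()) {
  zs <- contour_zs(contours)
  pz <- contour_zs(planning_contours)
  ratio <- vapply(seq_along(zs), function(i) {
    j <- which.min(abs(pz - zs[i]))
    poly_area(contours$contours[[i]]$vertices) /
      poly_area(planning_contours$contours[[j]]$vertices)
  }, numeric(1))
  flagged <- ratio > params$inferior_area_ratio
  replaced <- rep(FALSE, length(zs))
  if (any(flagged)) {
    top <- max(which(flagged))          # contours are sorted by z
    replaced[seq_len(top)] <- TRUE
    for (i in seq_len(top)) {
      j <- which.min(abs(pz - zs[i]))
      contours$contours[[i]]$vertices <-
        planning_contours$contours[[j]]$vertices
    }
  }
  attr(contours, "replaced") <- replaced
  contours
}

# radial resampling of the contour stack: smoothed centroids and per-ray
# radii via leave-one-out moving polynomial fits across slices
.radial_model <- function(cs, params) {
  n <- length(cs$contours)
  th <- 2 * pi * (seq_len(params$n_rays) - 1) / params$n_rays
  dirs <- cbind(cos(th), sin(th))
  cents <- t(vapply(cs$contours, function(ct) poly_centroid(ct$vertices),
                    numeric(2)))
  loo_fit <- function(y, i, h) {
    j <- setdiff(max(1, i - h):min(n, i + h), i)
    j <- j[is.finite(y[j])]
    if (length(j) < 2) return(y[i])
    # interior slices: leave-one-out linear fit; edge slices: window mean
    # (one-sided linear extrapolation amplifies radius noise severalfold)
    if (any(j < i) && any(j > i)) {
      fit <- stats::lm(yy ~ jj, data = data.frame(yy = y[j], jj = j))
      unname(stats::predict(fit, data.frame(jj = i)))
    } else mean(y[j])
  }
  h <- max(1, (params$smooth_span - 1) %/% 2)
  sc <- cents
  for (i in seq_len(n)) {
    sc[i, 1] <- loo_fit(cents[, 1], i, h)
    sc[i, 2] <- loo_fit(cents[, 2], i, h)
  }
  # radii about each slice's own centroid: centroid drift must not
  # masquerade as shape deviation
  rad <- matrix(NA_real_, n, params$n_rays)
  for (i in seq_len(n))
    for (k in seq_len(params$n_rays))
      rad[i, k] <- poly_ray_intersect(cs$contours[[i]]$vertices, cents[i, ],
                                      dirs[k, ])
  srad <- rad
  for (k in seq_len(params$n_rays))
    for (i in seq_len(n)) srad[i, k] <- loo_fit(rad[, k], i, h)
  list(theta = th, dirs = dirs, centroids = cents, s_centroids = sc,
       radii = rad, s_radii = srad)
}

#' Replace outlier slices by the smoothed three-dimensional surface
#'
#' Each contour is resampled to fixed angular rays from a smoothed centroid
#' track; per-ray radii are smoothed across slices with a leave-one-out
#' moving linear fit over `smooth_span` slices.  A slice whose mean radial
#' deviation from the smoothed surface exceeds `surface_dev_mm` is replaced
#' by the smoothed contour.  The operation is idempotent at the stated
#' tolerance.
#'
#' @param contours a [contour_set()] with at least 3 slices.
#' @param params a [seg_params()].
#' @return a [contour_set()] with attributes `replaced` and `deviation`.
#' @export
surface_smooth_replace <- function(contours, params = seg_params()) {
  n <- length(contours$contours)
  if (n < 3) stop("need at least 3 slices to form a smoothed surface")
  md <- .radial_model(contours, params)
  dev <- rowMeans(abs(md$radii - md$s_radii), na.rm = TRUE) +
    sqrt(rowSums((md$centroids - md$s_centroids)^2))
  replaced <- is.finite(dev) & dev > params$surface_dev_mm
  for (i in which(replaced)) {
    r <- md$s_radii[i, ]
    r[!is.finite(r) | r <= 0] <- mean(r[is.finite(r) & r > 0])
    contours$contours[[i]]$vertices <-
      cbind(md$s_centroids[i, 1] + r * md$dirs[, 1],
            md$s_centroids[i, 2] + r * md$dirs[, 2])
  }
  attr(contours, "replaced") <- replaced
  attr(contours, "deviation") <- dev
  contours
}

#' Conformity index (Jaccard) between two masks
#'
#' `|A intersect B| / |A union B|`.  This toolkit's conformity index is the
#' Jaccard coefficient; Dice would give systematically different numbers.
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return value in `[0, 1]`.
#' @export
conformity_index <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("masks must share a grid")
  u <- sum(mask_a | mask_b)
  if (u == 0) stop("both masks are empty")
  sum(mask_a & mask_b) / u
}

#' Rasterise a polygon onto a voxel grid
#'
#' A voxel belongs to the mask when its centre lies inside the polygon.
#'
#' @param poly n x 2 vertex matrix (mm).
#' @param xs,ys voxel-centre coordinate vectors (mm).
#' @return logical matrix `[length(ys), length(xs)]`.
#' @export
polygon_to_mask <- function(poly, xs, ys) {
  g <- expand.grid(y = ys, x = xs)
  inside <- pracma::inpolygon(g$x, g$y, poly[, 1], poly[, 2])
  matrix(inside, nrow = length(ys), ncol = length(xs))
}

# marching-squares polygon (0.5 level) from a binary mask; returns the ring
# containing `hint`, or NULL
mask_to_polygon <- function(mask, xs, ys, hint) {
  pm <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pm[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  yy <- c(ys[1] - dy, ys, ys[length(ys)] + dy)
  xx <- c(xs[1] - dx, xs, xs[length(xs)] + dx)
  cl <- grDevices::contourLines(x = yy, y = xx, z = pm, levels = 0.5)
  if (!length(cl)) return(NULL)
  polys <- lapply(cl, function(l) cbind(l$y, l$x))   # back to (x, y)
  keep <- vapply(polys, function(p)
    pracma::inpolygon(hint[1], hint[2], p[, 1], p[, 2]), logical(1))
  cand <- if (any(keep)) polys[keep] else polys
  p <- cand[[which.max(vapply(cand, poly_area, numeric(1)))]]
  if (nrow(p) > 1 && isTRUE(all.equal(p[1, ], p[nrow(p), ])))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) return(NULL)
  p
}

#' Rasterise a contour set onto a volume grid
#'
#' @param cs a [contour_set()].
#' @param vol an [image_volume()] or [dose_cube()] supplying the grid.
#' @return logical array with the volume's dimensions.
#' @export
contours_to_mask <- function(cs, vol) {
  d <- dim_of(vol)
  xs <- vol_x(vol); ys <- vol_y(vol)
  dz <- if (d[3] > 1) slice_spacing(vol) else 6
  out <- array(FALSE, d)
  zs <- contour_zs(cs)
  for (s in seq_len(d[3])) {
    hit <- which(abs(zs - vol$slice_positions[s]) <= dz / 2 + 1e-6)
    for (i in hit)
      out[, , s] <- out[, , s] | polygon_to_mask(cs$contours[[i]]$vertices,
                                                 xs, ys)
  }
  out
}

# map planning contours into the MV frame using the registration
transform_contours <- function(cs, reg, isocentre = c(0, 0)) {
  cs$contours <- lapply(cs$contours, function(ct) {
    ct$vertices <- rot2(ct$vertices, -reg$roll, isocentre)
    ct$vertices[, 1] <- ct$vertices[, 1] + reg$dx
    ct$vertices[, 2] <- ct$vertices[, 2] + reg$dy
    ct$z <- ct$z + reg$dz
    ct
  })
  cs
}

#' Segment the rectum on every slice of an MV scan
#'
#' Per-slice pipeline: map the planning contour into the MV frame with the
#' registration, preprocess (air remap + window), run the Chan-Vese level
#' set on a cropped working region seeded from the planning contour,
#' convert the mask back to a polygon, then apply the inferior replacement
#' and the smoothed-surface outlier replacement.
#'
#' @param mv the MV [image_volume()].
#' @param planning_contours planning rectum [contour_set()] (planning
#'   frame).
#' @param params a [seg_params()].
#' @param reg the fraction's [registration()]; unusable fractions are
#'   refused.
#' @param isocentre in-plane isocentre (mm) used for the roll mapping.
#' @return a [contour_set()]; attribute `stages` holds the intermediate
#'   contour sets (`raw` = level-set output, `fixed` = after the inferior
#'   replacement) for auditing.
#' @export
segment_scan <- function(mv, planning_contours, params = seg_params(),
                         reg = registration(), isocentre = c(0, 0)) {
  if (!reg$usable) stop("fraction skipped: registration flagged unusable")
  plan_cs <- transform_contours(planning_contours, reg, isocentre)
  pz <- contour_zs(plan_cs)
  xs <- vol_x(mv); ys <- vol_y(mv)
  out <- list()
  for (s in seq_len(dim(mv$voxels)[3])) {
    z <- mv$slice_positions[s]
    if (z < min(pz) - 3 || z > max(pz) + 3) next
    init_poly <- plan_cs$contours[[which.min(abs(pz - z))]]$vertices
    img <- preprocess_slice(mv$voxels[, , s], params)
    # working region: planning bounding box + margin
    cidx <- which(xs >= min(init_poly[, 1]) - params$crop_margin &
                    xs <= max(init_poly[, 1]) + params$crop_margin)
    ridx <- which(ys >= min(init_poly[, 2]) - params$crop_margin &
                    ys <= max(init_poly[, 2]) + params$crop_margin)
    if (!length(cidx) || !length(ridx)) next
    crop <- img[ridx, cidx, drop = FALSE]
    init <- polygon_to_mask(init_poly, xs[cidx], ys[ridx])
    if (!any(init)) next
    mask <- chan_vese_slice(crop, init, params)
    poly <- mask_to_polygon(mask, xs[cidx], ys[ridx],
                            poly_centroid(init_poly))
    if (is.null(poly)) poly <- init_poly
    out[[length(out) + 1L]] <- list(z = z, vertices = poly)
  }
  if (!length(out))
    stop("planning rectum does not overlap the MV scan extent")
  raw <- contour_set(out, structure_name = planning_contours$structure_name,
                     frame_of_reference = mv$frame_of_reference)
  fixed <- fix_inferior(raw, plan_cs, params)
  final <- if (length(fixed$contours) >= 3)
    surface_smooth_replace(fixed, params) else fixed
  attr(final, "stages") <- list(raw = raw, fixed = fixed)
  final
}
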