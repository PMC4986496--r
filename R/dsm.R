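# Dose-surface maps: each rectal contour is treated as a cylinder
# cross-section, cut at the point where the vertical line through the
# centroid crosses the posterior edge, unfolded into a row of equally
# arc-length-spaced dose samples, and accumulated across fractions on a
# fixed SI lattice with planning-CT padding where the short MV scan gives
# no coverage.  Normalising every row to a fixed number of columns removes
# day-to-day circumference variation; the map stores physical dose at the
# normalised angular coordinate.

#' Dose-surface map container
#'
#' @param values Gy matrix `[row, column]`; rows are SI slice positions,
#'   columns equally spaced points around the unfolded surface.
#' @param row_si strictly increasing SI positions (mm), one per row.
#' @param circumference per-row contour circumference, mm.
#' @param provenance `"fraction"`, `"planning"` or `"accumulated"`.
#' @return object of class `dose_surface_map`.
#' @export
dose_surface_map <- function(values, row_si, circumference,
                             provenance = c("fraction", "planning",
                                            "accumulated")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (nrow(values) != length(row_si))
    stop("one SI position per row required")
  if (length(row_si) > 1 && any(diff(row_si) <= 0))
    stop("row_si must be strictly increasing")
  if (any(values < 0)) stop("DSM values must be non-negative")
  structure(list(values = values, row_si = as.numeric(row_si),
                 n_theta = ncol(values),
                 circumference = as.numeric(circumference),
                 provenance = provenance),
            class = "dose_surface_map")
}

#' @export
print.dose_surface_map <- function(x, ...) {
  cat(sprintf("<dose_surface_map> %s: %d rows x %d points, z %.1f..%.1f mm, max %.3g Gy\n",
              x$provenance, nrow(x$values), x$n_theta, min(x$row_si),
              max(x$row_si), max(x$values)))
  invisible(x)
}

#' Cut point of a contour for unfolding
#'
#' The intersection of the vertical ray from the centroid towards the
#' posterior edge with the polygon boundary; with several intersections the
#' one nearest the centroid is taken.  Cutting posterior of the centroid --
#' rather than at the most posterior boundary point -- keeps the central
#' DSM column on the middle of the anterior rectal wall and avoids large
#' slice-to-slice jumps.
#'
#' @param poly n x 2 vertex matrix (mm).
#' @param posterior unit direction of "posterior" in the contour plane.
#'   The default `c(0, -1)` matches the y-up display convention; callers
#'   working in DICOM LPS coordinates (y = posterior) should pass
#'   `c(0, 1)`.
#' @return list with `point` (x, y) and `distance` from the centroid.
#' @export
cut_point <- function(poly, posterior = c(0, -1)) {
  ctr <- poly_centroid(poly)
  t <- poly_ray_intersect(poly, ctr, posterior)
  if (is.na(t))
    stop("no posterior boundary intersection from the centroid")
  list(point = ctr + t * posterior, distance = t)
}

# resample a closed polygon to n points equally spaced by arc length,
# starting at arc-length position s0, in the parameterisation's direction
.resample_closed <- function(poly, n, s0 = 0, reverse = FALSE) {
  if (reverse) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  al <- poly_arclength(poly)
  if (al$total <= 0) stop("degenerate (zero-perimeter) contour")
  s <- (s0 + al$total * (seq_len(n) - 1) / n) %% al$total
  vx <- c(poly[, 1], poly[1, 1]); vy <- c(poly[, 2], poly[1, 2])
  sv <- c(al$s, al$total)
  cbind(stats::approx(sv, vx, xout = s)$y,
        stats::approx(sv, vy, xout = s)$y)
}

# arc-length position of the point on the polygon boundary closest to p
.arc_position <- function(poly, p) {
  al <- poly_arclength(poly)
  v <- rbind(poly, poly[1, ])
  best <- c(Inf, 0)
  for (i in seq_len(nrow(poly))) {
    a <- v[i, ]; b <- v[i + 1, ]; e <- b - a
    L2 <- sum(e^2)
    t <- if (L2 > 0) max(0, min(1, sum((p - a) * e) / L2)) else 0
    q <- a + t * e
    d <- sum((p - q)^2)
    if (d < best[1]) best <- c(d, al$s[i] + t * sqrt(L2))
  }
  best[2]
}

#' Unfold one contour into a DSM row
#'
#' Samples the dose at `n_theta` points equally spaced by arc length around
#' the contour, starting at the cut point and proceeding patient-left
#' first; the dose plane is interpolated bilinearly.  Fixing `n_theta`
#' normalises away day-to-day circumference changes.
#'
#' @param poly n x 2 vertex matrix (mm, LPS in-plane).
#' @param dose_plane numeric matrix of dose (Gy) on the plane.
#' @param xs,ys voxel-centre coordinates of the dose plane (mm).
#' @param n_theta number of sample points.
#' @param posterior posterior direction passed to [cut_point()].
#' @return list with `row` (Gy vector of length `n_theta`),
#'   `circumference` (mm) and `points` (n_theta x 2 sample positions).
#' @export
unfold_slice <- function(poly, dose_plane, xs, ys, n_theta = 21,
                         posterior = c(0, 1)) {
  if (min(poly[, 1]) < min(xs) || max(poly[, 1]) > max(xs) ||
      min(poly[, 2]) < min(ys) || max(poly[, 2]) > max(ys))
    stop("dose plane does not cover the contour bounding box")
  al <- poly_arclength(poly)
  if (al$total <= 0) stop("degenerate (zero-perimeter) contour")
  cp <- cut_point(poly, posterior)
  # choose the traversal direction that moves patient-left (+x) first
  s_fwd <- .arc_position(poly, cp$point)
  fwd <- .resample_closed(poly, n_theta, s_fwd, reverse = FALSE)
  rpoly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  s_rev <- .arc_position(rpoly, cp$point)
  rev_ <- .resample_closed(rpoly, n_theta, s_rev, reverse = FALSE)
  probe <- max(2L, min(4L, n_theta))
  pts <- if (fwd[2, 1] + fwd[probe, 1] >= rev_[2, 1] + rev_[probe, 1])
    fwd else rev_
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  row <- cpp_bilinear(dose_plane, (pts[, 2] - ys[1]) / dy,
                      (pts[, 1] - xs[1]) / dx, 0)
  list(row = as.numeric(row), circumference = al$total, points = pts)
}

#' Build the DSM of one fraction
#'
#' One row per contoured slice; row SI positions are the slice z corrected
#' by the fraction's SI shift, and rows are ordered by SI regardless of the
#' input order.
#'
#' @param cs rectum [contour_set()] on the fraction's image.
#' @param cube the fraction's [dose_cube()] (same frame).
#' @param n_theta sample points per row.
#' @param dz SI shift (mm) applied at treatment for this fraction; rows are
#'   reported at `z - dz` so all fractions share the planning SI axis.
#' @return a [dose_surface_map()] with provenance `"fraction"`.
#' @export
build_fraction_dsm <- function(cs, cube, n_theta = 21, dz = 0) {
  xs <- vol_x(cube); ys <- vol_y(cube)
  zc <- cube$slice_positions
  rows <- list()
  for (ct in cs$contours) {
    s <- which.min(abs(zc - ct$z))
    if (abs(zc[s] - ct$z) > slice_spacing(cube) / 2 + 1e-6)
      stop(sprintf("no dose coverage for contour slice at z = %.1f mm",
                   ct$z))
    u <- unfold_slice(ct$vertices, cube$dose[, , s], xs, ys, n_theta)
    rows[[length(rows) + 1L]] <- list(si = ct$z - dz, row = u$row,
                                      circ = u$circumference)
  }
  si <- vapply(rows, `[[`, numeric(1), "si")
  ord <- order(si)
  dose_surface_map(do.call(rbind, lapply(rows[ord], `[[`, "row")),
                   row_si = si[ord],
                   circumference = vapply(rows[ord], `[[`, numeric(1),
                                          "circ"),
                   provenance = "fraction")
}

#' Accumulate per-fraction DSMs with planning padding
#'
#' Accumulation rows live on a fixed lattice (default 6 mm) spanning the
#' rectum's SI extent.  For each fraction and lattice row, the fraction
#' contributes its nearest-row values where it has coverage and the
#' per-fraction planning row values where it does not; the output is the
#' sum over fractions.  A full-course planning DSM should be divided by the
#' planned number of fractions before being passed.
#'
#' @param fraction_dsms list of [dose_surface_map()]s.
#' @param planning_dsm per-fraction planning [dose_surface_map()] spanning
#'   the extent.
#' @param rectum_si_extent length-2 (min, max) SI extent, mm.
#' @param lattice_mm row spacing of the accumulation lattice.
#' @return a [dose_surface_map()] with provenance `"accumulated"`.
#' @export
accumulate_dsms <- function(fraction_dsms, planning_dsm, rectum_si_extent,
                            lattice_mm = 6) {
  nth <- planning_dsm$n_theta
  for (f in fraction_dsms)
    if (f$n_theta != nth) stop("n_theta mismatch between maps")
  si <- seq(rectum_si_extent[1], rectum_si_extent[2], by = lattice_mm)
  if (min(planning_dsm$row_si) > si[1] + lattice_mm / 2 ||
      max(planning_dsm$row_si) < si[length(si)] - lattice_mm / 2)
    stop("planning DSM does not span the rectum SI extent")
  nearest_row <- function(dsm, z, tol) {
    i <- which.min(abs(dsm$row_si - z))
    if (abs(dsm$row_si[i] - z) <= tol) i else NA_integer_
  }
  acc <- matrix(0, length(si), nth)
  circ <- numeric(length(si))
  for (r in seq_along(si)) {
    pi_ <- nearest_row(planning_dsm, si[r], lattice_mm)
    for (f in fraction_dsms) {
      fi <- nearest_row(f, si[r], lattice_mm / 2)
      if (!is.na(fi)) {
        acc[r, ] <- acc[r, ] + f$values[fi, ]
        circ[r] <- f$circumference[fi]
      } else if (!is.na(pi_)) {
        acc[r, ] <- acc[r, ] + planning_dsm$values[pi_, ]
        if (circ[r] == 0) circ[r] <- planning_dsm$circumference[pi_]
      } else {
        stop(sprintf("no fraction or planning coverage at SI %.1f mm",
                     si[r]))
      }
    }
  }
  dose_surface_map(acc, si, circ, provenance = "accumulated")
}

#' Generalized equivalent uniform dose
#'
#' `gEUD = (mean(d^a))^(1/a)` over all map points.  Uniform dose D gives D
#' for any `a`; `a = 1` is the arithmetic mean; large `a` approaches the
#' maximum.  For `a < 0` a zero dose anywhere drives the power mean to its
#' limit 0, which is returned with a warning.
#'
#' @param x a [dose_surface_map()] or a numeric vector/matrix of doses
#'   (Gy, non-negative).
#' @param a Niemierko volume-effect parameter; must be non-zero.
#' @return gEUD in Gy.
#' @export
geud <- function(x, a) {
  v <- if (inherits(x, "dose_surface_map")) as.numeric(x$values)
       else as.numeric(x)
  if (!length(v)) stop("empty dose input")
  if (a == 0) stop("a must be non-zero")
  if (any(v < 0)) stop("doses must be non-negative")
  if (a < 0 && any(v == 0)) {
    warning("zero dose with a < 0: gEUD limit is 0")
    return(0)
  }
  mean(v^a)^(1 / a)
}

#' Delivered-to-planned gEUD ratio
#'
#' @param delivered_dsm,planned_dsm [dose_surface_map()]s.
#' @param a gEUD parameter.  The rectum convention used by the
#'   command-line tools is `a = 8`; it is a convention of this toolkit,
#'   not a measured value.
#' @return `geud(delivered) / geud(planned)`.
#' @export
relative_eud <- function(delivered_dsm, planned_dsm, a = 8) {
  pe <- geud(planned_dsm, a)
  if (pe <= 0) stop("planned EUD is zero")
  geud(delivered_dsm, a) / pe
}

#' Write / read a DSM as CSV
#'
#' Rows carry `si_mm`, `circumference_mm`, `provenance` metadata columns
#' followed by the `n_theta` dose columns.
#'
#' @param dsm a [dose_surface_map()].
#' @param path CSV file.
#' @return `write_dsm_csv`: the path, invisibly; `read_dsm_csv`: a
#'   [dose_surface_map()].
#' @export
write_dsm_csv <- function(dsm, path) {
  df <- data.frame(si_mm = dsm$row_si,
                   circumference_mm = dsm$circumference,
                   provenance = dsm$provenance)
  df <- cbind(df, as.data.frame(dsm$values))
  names(df)[-(1:3)] <- sprintf("theta_%02d", seq_len(dsm$n_theta))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsm_csv
#' @export
read_dsm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, grep("^theta_", names(df)), drop = FALSE])
  dimnames(vals) <- NULL
  dose_surface_map(vals, df$si_mm, df$circumference_mm,
                   provenance = df$provenance[1])
}
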