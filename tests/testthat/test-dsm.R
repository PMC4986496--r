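test_that("cut point lies posterior of the centroid on the boundary", {
  circle <- regular_polygon(30, c(0, 0), 200)
  cp <- cut_point(circle)                       # default posterior = (0,-1)
  expect_equal(cp$point, c(0, -30), tolerance = 1e-6)
  # square: midpoint of the posterior edge
  sq <- rbind(c(-10, -10), c(10, -10), c(10, 10), c(-10, 10))
  expect_equal(cut_point(sq)$point, c(0, -10), tolerance = 1e-9)
  # LPS convention: posterior is +y
  expect_equal(cut_point(circle, posterior = c(0, 1))$point, c(0, 30),
               tolerance = 1e-6)
})

test_that("cut point of an offset ellipse matches a dense boundary scan", {
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  ell <- cbind(3 + 20 * cos(th), -5 + 12 * sin(th) + 4 * cos(2 * th))
  cp <- cut_point(ell)
  # brute force: walk the boundary at 1e5 points, find where the downward
  # vertical from the centroid crosses it
  ctr <- voxcalc:::poly_centroid(ell)
  vc <- rbind(ell, ell[1, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], length.out = 1e5)
  bx <- approx(s, vc[, 1], xout = t)$y
  by <- approx(s, vc[, 2], xout = t)$y
  cand <- which(abs(bx - ctr[1]) < 0.02 & by < ctr[2])
  best <- cand[which.min(ctr[2] - by[cand])]
  expect_lt(sqrt(sum((cp$point - c(bx[best], by[best]))^2)), 0.1)
})

test_that("unfolding samples dose at equal arc lengths from the cut", {
  gx <- seq(-50, 50, by = 2)
  circle <- regular_polygon(30, c(0, 0), 360)
  # uniform dose -> constant row
  u <- unfold_slice(circle, matrix(5, 51, 51), gx, gx, n_theta = 21,
                    posterior = c(0, -1))
  expect_equal(u$row, rep(5, 21))
  expect_equal(u$circumference, 2 * pi * 30, tolerance = 0.1)
  # linear gradient D = 10 + 0.1 y -> sinusoid -0.1 r cos(2 pi k / n)
  plane <- outer(gx, gx, function(y, x) 10 + 0.1 * y)
  u2 <- unfold_slice(circle, plane, gx, gx, n_theta = 24,
                     posterior = c(0, -1))
  k <- 0:23
  expect_equal(u2$row, 10 + 0.1 * (-30 * cos(2 * pi * k / 24)),
               tolerance = 0.01)
  # first step proceeds patient-left (+x)
  expect_gt(u2$points[2, 1], u2$points[1, 1])
  # arc-length spacing against dense re-parameterisation
  gaps <- sqrt(rowSums(diff(rbind(u2$points, u2$points[1, ]))^2))
  per <- u2$circumference
  expect_lt(max(abs(gaps - per / 24)), per / (10 * 24))
  # degenerate contour rejected
  degen <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_error(unfold_slice(degen, plane, gx, gx), "degenerate")
})

test_that("fraction DSMs carry shift-corrected, ordered SI rows", {
  dose <- dose_cube(array(2, c(30, 30, 5)), c(-29, -29),
                    c(2, 2), (0:4) * 6)
  cs <- contour_set(list(
    list(z = 12, vertices = regular_polygon(8, c(0, 0))),
    list(z = 0, vertices = regular_polygon(8, c(0, 0))),
    list(z = 6, vertices = regular_polygon(8, c(0, 0)))))
  dsm <- build_fraction_dsm(cs, dose, n_theta = 11)
  expect_equal(nrow(dsm$values), 3)
  expect_equal(dsm$row_si, c(0, 6, 12))          # ordered by SI
  expect_equal(unique(as.numeric(dsm$values)), 2)
  dsm2 <- build_fraction_dsm(cs, dose, n_theta = 11, dz = 6)
  expect_equal(dsm2$row_si, c(0, 6, 12) - 6)
  # a contour with no dose plane within half a slice spacing errors
  cs_far <- contour_set(list(list(z = 100,
                                  vertices = regular_polygon(8, c(0, 0)))))
  expect_error(build_fraction_dsm(cs_far, dose), "coverage")
})

test_that("accumulation pads the uncovered rows from the planning DSM", {
  nth <- 12
  mk <- function(si, val, prov = "fraction")
    dose_surface_map(matrix(val, length(si), nth), si,
                     rep(60, length(si)), provenance = prov)
  planning <- mk(seq(-30, 36, by = 6), 1, "planning")
  # single fraction fully covering the extent
  f1 <- mk(seq(-30, 36, by = 6), 2)
  acc1 <- accumulate_dsms(list(f1), planning, c(-30, 36))
  expect_equal(acc1$values, f1$values)
  # N identical fractions scale elementwise
  acc3 <- accumulate_dsms(list(f1, f1, f1), planning, c(-30, 36))
  expect_equal(acc3$values, 3 * f1$values)
  # fraction covering rows 3-8 of 12: outside rows take planning values
  si <- seq(-30, 36, by = 6)
  fpart <- mk(si[3:8], 5)
  accp <- accumulate_dsms(list(fpart), planning, c(-30, 36))
  expect_equal(accp$values[3:8, ], matrix(5, 6, nth))
  expect_equal(accp$values[c(1, 2, 9:12), ], matrix(1, 6, nth))
  # permutation invariance and linearity in the fraction list
  f2 <- mk(si, 0.5)
  a12 <- accumulate_dsms(list(f1, f2), planning, c(-30, 36))
  a21 <- accumulate_dsms(list(f2, f1), planning, c(-30, 36))
  expect_equal(a12$values, a21$values)
  expect_equal(a12$values, f1$values + f2$values)
  # n_theta mismatch errors
  bad <- dose_surface_map(matrix(1, 12, 7), si, rep(60, 12))
  expect_error(accumulate_dsms(list(bad), planning, c(-30, 36)),
               "n_theta")
})

test_that("gEUD follows the Niemierko power mean", {
  expect_equal(geud(rep(3.3, 50), 8), 3.3)       # uniform dose
  v <- c(0.5, 1.2, 2, 2.8)
  expect_equal(geud(v, 1), mean(v))              # a = 1 is the mean
  expect_equal(geud(c(1, 3), 2), sqrt(5))        # hand computation
  # homogeneity
  expect_equal(geud(2.5 * v, 3.7), 2.5 * geud(v, 3.7))
  # power-mean monotonicity and bounds for a >= 1
  as <- c(1, 2, 4, 8, 16, 50)
  gs <- vapply(as, function(a) geud(v, a), numeric(1))
  expect_true(all(diff(gs) >= -1e-12))
  expect_true(all(gs >= min(v) & gs <= max(v)))
  # large a approaches the maximum within 0.1% on a plateaued map (most
  # of the surface near the maximum, as on the anterior rectal wall)
  plateau <- c(rep(2, 950), seq(0.5, 1.9, length.out = 50))
  expect_lt(abs(geud(plateau, 100) - 2) / 2, 0.001)
  # zeros with negative a give the limit 0 with a warning
  expect_warning(z <- geud(c(0, 1, 2), -1), "limit")
  expect_equal(z, 0)
  expect_error(geud(numeric(0), 2), "empty")
  expect_error(geud(v, 0), "non-zero")
})

test_that("relative EUD is scale-true and matches direct recomputation", {
  set.seed(8)
  mkmap <- function(vals) dose_surface_map(vals, seq_len(nrow(vals)) * 6,
                                           rep(50, nrow(vals)))
  m <- mkmap(matrix(runif(8 * 21, 0.5, 2.5), 8))
  expect_equal(relative_eud(m, m, 8), 1)
  s <- m; s$values <- 0.97 * m$values
  for (a in c(1, 4, 8)) expect_equal(relative_eud(s, m, a), 0.97)
  m2 <- mkmap(matrix(runif(8 * 21, 0.5, 2.5), 8))
  expect_equal(relative_eud(m2, m, 5),
               mean(m2$values^5)^(1 / 5) / mean(m$values^5)^(1 / 5))
})

test_that("unfolding is equivariant under rotations by whole columns", {
  gx <- seq(-50, 50, by = 1)
  n_theta <- 24
  circle <- regular_polygon(30, c(0, 0), 360)
  plane <- outer(gx, gx, function(y, x) 10 + 0.08 * y + 0.03 * x)
  u0 <- unfold_slice(circle, plane, gx, gx, n_theta, posterior = c(0, -1))
  # rotate contour and dose field by one column's angle; the circle maps to
  # itself and the cut convention fixes the start, so the row equals the
  # original sampled at rotated positions
  th <- -2 * pi / n_theta
  plane_r <- outer(gx, gx, function(y, x) {
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    10 + 0.08 * yr + 0.03 * xr
  })
  u1 <- unfold_slice(circle, plane_r, gx, gx, n_theta, posterior = c(0, -1))
  expect_equal(u1$row, u0$row[c(n_theta, 1:(n_theta - 1))],
               tolerance = 1e-6)
})

test_that("DSM CSV round-trips values and metadata", {
  set.seed(9)
  dsm <- dose_surface_map(matrix(runif(5 * 21, 0, 3), 5),
                          seq(-12, 12, by = 6), runif(5, 50, 80),
                          provenance = "accumulated")
  f <- withr::local_tempfile(fileext = ".csv")
  write_dsm_csv(dsm, f)
  d2 <- read_dsm_csv(f)
  expect_equal(d2$values, dsm$values, tolerance = 1e-12)
  expect_equal(d2$row_si, dsm$row_si)
  expect_equal(d2$circumference, dsm$circumference, tolerance = 1e-12)
  expect_identical(d2$provenance, "accumulated")
})
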