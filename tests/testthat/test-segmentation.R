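test_that("preprocessing remaps gas to rectal material and preserves order", {
  p <- seg_params()
  # a pixel just below the air threshold maps exactly like rectal material
  img <- matrix(c(p$air_threshold - 1, p$rectal_hu, -50, 100), 2, 2)
  out <- preprocess_slice(img, p)
  expect_equal(out[1, 1], out[2, 1])
  # rectal-material pixels are untouched by the remap
  expect_equal(out[2, 1],
               (p$rectal_hu - p$window_low) / (p$window_high - p$window_low))
  # monotone inside the window
  v <- seq(p$window_low, p$window_high, by = 10)
  expect_true(all(diff(preprocess_slice(matrix(v, 1), p)) > 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("Chan-Vese recovers a piecewise-constant disk from a rough seed", {
  set.seed(12)
  n <- 60
  d2 <- outer(1:n - 30, 1:n - 30, function(a, b) a^2 + b^2)
  truth <- d2 < 15^2
  img <- ifelse(truth, 0.8, 0.2) + rnorm(n * n, 0, 0.04)
  # symmetric classical energy for the solver check
  p <- seg_params(lambda2 = 1)
  for (init in list(d2 < 9^2,
                    outer(1:n - 37, 1:n - 28,
                          function(a, b) a^2 + b^2) < 15^2)) {
    m <- chan_vese_slice(img, init, p)
    expect_gte(sum(m & truth) / sum(m | truth), 0.98)
  }
  # fixed point: init equal to the true region on a clean image
  clean <- ifelse(truth, 0.8, 0.2)
  m2 <- chan_vese_slice(clean, truth, p)
  expect_gte(sum(m2 & truth) / sum(m2 | truth), 0.98)
  # uniform image returns the init mask
  d2s <- outer(1:20 - 10, 1:20 - 10, function(a, b) a^2 + b^2)
  expect_identical(chan_vese_slice(matrix(0.5, 20, 20), d2s < 8^2),
                   d2s < 8^2)
  expect_error(chan_vese_slice(clean, matrix(FALSE, n, n)), "empty")
})

test_that("fix_inferior replaces up to the most superior flagged slice", {
  p <- seg_params()  # threshold 1.5
  mk <- function(radii) contour_set(lapply(seq_along(radii), function(i)
    list(z = (i - 1) * 6, vertices = regular_polygon(radii[i], c(0, 60)))))
  planning <- mk(rep(10, 10))
  # areas 2x planning (radius sqrt(2)x) on slices 1-3 of 10
  auto <- mk(c(rep(10 * sqrt(2), 3), rep(10, 7)))
  fixed <- fix_inferior(auto, planning, p)
  expect_equal(attr(fixed, "replaced"),
               c(rep(TRUE, 3), rep(FALSE, 7)))
  for (i in 1:3)
    expect_equal(fixed$contours[[i]]$vertices,
                 planning$contours[[i]]$vertices)
  for (i in 4:10)
    expect_equal(fixed$contours[[i]]$vertices, auto$contours[[i]]$vertices)
  # no flagged slices: output identical
  clean <- fix_inferior(mk(rep(10, 10)), planning, p)
  expect_false(any(attr(clean, "replaced")))
  # flagged slice at the top: all slices replaced
  top <- mk(c(rep(10, 9), 20))
  expect_true(all(attr(fix_inferior(top, planning, p), "replaced")))
})

test_that("surface smoothing replaces constructed outliers and only them", {
  p <- seg_params()  # threshold 3 mm
  mk <- function(radii) contour_set(lapply(seq_along(radii), function(i)
    list(z = (i - 1) * 6, vertices = regular_polygon(radii[i], c(0, 60)))))
  # identical circles: unchanged within resampling tolerance
  same <- surface_smooth_replace(mk(rep(12, 8)), p)
  expect_false(any(attr(same, "replaced")))
  # one slice dilated by 8 mm: replaced, with radius near its neighbours
  out <- surface_smooth_replace(mk(c(12, 12, 12, 20, 12, 12, 12, 12)), p)
  expect_equal(which(attr(out, "replaced")), 4L)
  repl <- out$contours[[4]]$vertices
  radii <- sqrt((repl[, 1])^2 + (repl[, 2] - 60)^2)
  expect_lt(max(abs(radii - 12)), 1)
  # smoothly tapering stack: none replaced
  taper <- surface_smooth_replace(mk(seq(8, 15, by = 1)), p)
  expect_false(any(attr(taper, "replaced")))
  # idempotence at tolerance: second pass changes nothing
  twice <- surface_smooth_replace(out, p)
  expect_false(any(attr(twice, "replaced")))
  expect_error(surface_smooth_replace(mk(c(10, 10)), p), "3 slices")
})

test_that("conformity index is Jaccard with its boundary cases", {
  a <- array(FALSE, c(10, 10, 2)); b <- a
  a[2:5, 2:5, 1] <- TRUE
  expect_equal(conformity_index(a, a), 1)
  b[7:9, 7:9, 2] <- TRUE
  expect_equal(conformity_index(a, b), 0)
  expect_equal(conformity_index(b, a), 0)          # symmetric
  expect_error(conformity_index(a & FALSE, b & FALSE), "empty")
  # two unit squares overlapping half their area -> 1/3, by rasterisation
  xs <- seq(0.005, 2.495, by = 0.01)
  sq1 <- polygon_to_mask(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), xs, xs)
  sq2 <- polygon_to_mask(rbind(c(0.5, 0), c(1.5, 0), c(1.5, 1), c(0.5, 1)),
                         xs, xs)
  expect_equal(conformity_index(sq1, sq2), 1 / 3, tolerance = 0.01)
})

test_that("segment_scan reproduces an undeformed phantom rectum closely", {
  spec <- pelvis_spec(seed = 5, n_fractions = 1, shift_sd = 0,
                      dz_sd = 0, roll_sd = 0, radius_jitter_sd = 0,
                      gas_prob = 0, artifact_prob = 0, mv_noise_sd = 0,
                      low_contrast_below = -100)
  ser <- make_pelvis_series(spec)
  fr <- ser$fractions[[1]]
  seg <- segment_scan(fr$mv, ser$planning_contours, reg = fr$reg)
  expect_gte(scan_jaccard(seg, fr), 0.95)
})

test_that("segment_scan handles the study-condition phantom", {
  spec <- pelvis_spec(seed = 6, n_fractions = 1)
  ser <- make_pelvis_series(spec)
  fr <- ser$fractions[[1]]
  seg <- segment_scan(fr$mv, ser$planning_contours, reg = fr$reg)
  expect_gte(scan_jaccard(seg, fr), 0.8)
  # unusable fraction refused
  bad <- fr$reg; bad$usable <- FALSE
  expect_error(segment_scan(fr$mv, ser$planning_contours, reg = bad),
               "unusable")
  # no SI overlap errors
  far <- ser$planning_contours
  far$contours <- lapply(far$contours, function(ct) {
    ct$z <- ct$z + 500; ct
  })
  expect_error(segment_scan(fr$mv, far, reg = fr$reg), "overlap")
})
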