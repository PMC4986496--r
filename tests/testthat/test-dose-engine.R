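test_that("control-point expansion subdivides and applies roll", {
  plan <- helical_plan(matrix(0.5, 51, 64))
  cp <- expand_control_points(plan, roll = 0)
  expect_equal(nrow(cp), 51 * 7)
  expect_equal(unique(cp$weight), 1 / 7)
  # weights of each projection's subprojections sum to 1
  expect_equal(as.numeric(tapply(cp$weight, cp$projection, sum)),
               rep(1, 51))
  cp2 <- expand_control_points(plan, roll = 2)
  expect_equal(cp2$angle, cp$angle + 2)
  expect_equal(cp2$couch_z, cp$couch_z)
  # zero pitch keeps all couch positions equal
  plan0 <- helical_plan(matrix(0, 51, 64), pitch = 0)
  expect_equal(unique(expand_control_points(plan0, 0)$couch_z),
               plan0$couch_start)
  expect_error(expand_control_points(plan, 0, n_sub = 0), "n_sub")
})

test_that("beamlet model is normalized and linear in open time", {
  plan <- helical_plan(matrix(0, 51, 64), output_factor = 1.7)
  expect_equal(beamlet_dose(0, 50, 900, 2, plan), 0)
  expect_equal(beamlet_dose(1, 0, plan$source_axis_distance, 0, plan), 1.7)
  d1 <- beamlet_dose(0.3, 120, 800, 4, plan)
  expect_equal(beamlet_dose(0.6, 120, 800, 4, plan), 2 * d1)
  # attenuation and inverse square act in the expected directions
  expect_lt(beamlet_dose(1, 100, 850, 0, plan),
            beamlet_dose(1, 50, 850, 0, plan))
  expect_lt(beamlet_dose(1, 50, 1000, 0, plan),
            beamlet_dose(1, 50, 850, 0, plan))
})

test_that("fraction dose is linear in the sinogram and zero when closed", {
  line <- mv_line()
  ph <- make_cheese_phantom(cheese_spec(size = 64, spacing = 5,
                                        n_slices = 3), line)
  plan <- make_prostate_plan(target_center = c(0, 0, 0), target_radius = 25,
                             n_rotations = 2)
  closed <- plan; closed$leaf_open <- plan$leaf_open * 0
  c0 <- compute_fraction_dose(closed, ph$volume, NULL, registration(),
                              line, downsample = 4)
  expect_true(all(c0$dose == 0))
  half <- plan; half$leaf_open <- plan$leaf_open * 0.5
  ca <- compute_fraction_dose(plan, ph$volume, NULL, registration(), line,
                              downsample = 4)
  cb <- compute_fraction_dose(half, ph$volume, NULL, registration(), line,
                              downsample = 4)
  expect_equal(2 * cb$dose, ca$dose, tolerance = 1e-6)
  expect_gt(max(ca$dose), 0)
  # unusable fraction is refused with the skip reason
  expect_error(compute_fraction_dose(plan, ph$volume, NULL,
                                     registration(usable = FALSE), line),
               "unusable")
})

test_that("translation of phantom and isocentre together is equivariant", {
  line <- mv_line()
  ph <- make_cheese_phantom(cheese_spec(size = 64, spacing = 5,
                                        n_slices = 3), line)
  plan <- make_prostate_plan(target_center = c(0, 0, 0), target_radius = 25,
                             n_rotations = 2)
  c0 <- compute_fraction_dose(plan, ph$volume, NULL, registration(), line,
                              downsample = 4)
  # shift image origin and plan isocentre/target by the same vector
  sh <- c(15, -10)
  vol2 <- ph$volume; vol2$origin <- vol2$origin + sh
  plan2 <- make_prostate_plan(target_center = c(sh, 0), target_radius = 25,
                              n_rotations = 2, isocentre = sh)
  c2 <- compute_fraction_dose(plan2, vol2, NULL, registration(), line,
                              downsample = 4)
  expect_equal(c2$dose, c0$dose, tolerance = 1e-8)
})

test_that("box index matches the exhaustive search oracle", {
  set.seed(55)
  d <- c(12, 12, 4)
  sp <- c(2, 2, 6)
  base <- array(0, d)
  for (s in 1:d[3])
    base[, , s] <- outer(1:12, 1:12, function(i, j)
      2 * exp(-((i - 6)^2 + (j - 6)^2) / 18))
  mk <- function(a) dose_cube(a, c(0, 0), sp[1:2], (0:3) * 6)
  # identical cubes pass everywhere
  r <- box_index(mk(base), mk(base))
  expect_equal(r$pass_fraction, 1)
  # a 5% global offset on a uniform region fails in the flat interior
  flat <- array(1, d)
  r2 <- box_index(mk(flat), mk(flat * 1.05))
  expect_equal(r2$pass_fraction, 0)
  # randomly perturbed field agrees with the brute-force search
  pert <- base + array(rnorm(prod(d), 0, 0.05), d)
  pert <- pmax(pert, 0)
  el <- array(TRUE, d)
  r3 <- box_index(mk(base), mk(pert))
  o3 <- box_index_brute(base, pert, sp, 0.03, 3, el)
  expect_equal(r3$pass_fraction, o3$pass_fraction)
  expect_equal(r3$n_eval, o3$n_eval)
  # single perturbed voxel in a smooth field
  one <- base; one[6, 6, 2] <- one[6, 6, 2] * 1.2
  r4 <- box_index(mk(base), mk(one))
  o4 <- box_index_brute(base, one, sp, 0.03, 3, el)
  expect_equal(r4$pass_fraction, o4$pass_fraction)
  # empty evaluable set errors
  expect_error(box_index(mk(base), mk(base), body_mask = array(FALSE, d)),
               "evaluable")
})

test_that("plan files round-trip through the structured text format", {
  plan <- make_prostate_plan(n_rotations = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_plan(plan, f)
  p2 <- read_plan(f)
  expect_equal(p2$leaf_open, plan$leaf_open, tolerance = 1e-6)
  for (k in c("pitch", "gantry_start", "couch_start", "n_leaves",
              "leaf_width_at_iso", "fan_extent", "source_axis_distance",
              "output_factor", "mu_eff_cm"))
    expect_equal(p2[[k]], plan[[k]])
  expect_equal(p2$isocentre, plan$isocentre)
})

test_that("leaf-open fractions outside [0,1] are rejected", {
  expect_error(helical_plan(matrix(1.2, 51, 64)), "\\[0, 1\\]")
  expect_error(helical_plan(matrix(0, 51, 32)), "n_leaves")
})
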