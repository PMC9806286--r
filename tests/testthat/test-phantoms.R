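test_that("analytic volumes match closed forms and the quadrature oracle", {
  expect_equal(analytic_volume(sphere_phantom(1)), 4 * pi / 3,
               tolerance = 1e-12)

  # radius recovered by inverting 4/3 pi r^3 = 187.2 must give back 187.2
  r <- (3 * 187.2 / (4 * pi))^(1 / 3)
  expect_equal(analytic_volume(phantom_spec("ellipsoid", c(r, r, r))),
               187.2, tolerance = 1e-10)

  # superellipsoid with exponent 2 reduces to the sphere
  s2 <- phantom_spec("superellipsoid", c(1, 1, 1), exponent = 2)
  expect_equal(analytic_volume(s2), 4 * pi / 3, tolerance = 1e-12)

  # closed form vs the spherical quadrature oracle for a boxier exponent
  s3 <- phantom_spec("superellipsoid", c(2, 1.5, 4), exponent = 3)
  oracle <- local({  # Monte-Carlo membership integral, independent route
    set.seed(11)
    n <- 4e5
    pts <- cbind(runif(n, -2, 2), runif(n, -1.5, 1.5), runif(n, -4, 4))
    inside <- rowSums(abs(sweep(pts, 2, c(2, 1.5, 4), "/"))^3) <= 1
    mean(inside) * 4 * 3 * 8
  })
  expect_rel_equal(analytic_volume(s3), oracle, 0.01)

  # bumpy volume exceeds its base ellipsoid (cubic mean of 1 + A f > 1)
  bumpy <- phantom_spec("bumpy_ellipsoid", c(2, 1.5, 4), bump_amplitude = 0.2)
  base <- 4 / 3 * pi * 2 * 1.5 * 4
  expect_gt(analytic_volume(bumpy), base)
  expect_lt(analytic_volume(bumpy), base * 1.3^3)
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec("ellipsoid", c(1, -1, 1)))
  expect_error(phantom_spec("bumpy_ellipsoid", c(1, 1, 1),
                            bump_amplitude = 0.5), "bump_amplitude")
})

test_that("voxel count at fine resolution matches the analytic volume", {
  cfg <- voxel_config(pixel_spacing = c(0.1, 0.1), slice_thickness = 0.5,
                      slice_gap = 0, slice_offset = 0)
  v <- voxelize(sphere_phantom(3), cfg)
  vox_vol <- sum(v$mask$data) * 0.1 * 0.1 * 0.5
  expect_rel_equal(vox_vol, 4 * pi * 27 / 3, 0.01)
  # two-level image: foreground intensity 1000 over the mask
  expect_identical(unname(v$series$data[v$mask$data == 1][1]), 1000)
})

test_that("zero bump amplitude and exponent 2 degenerate to the ellipsoid", {
  cfg <- coarse_cfg(slice_offset = 0.1)
  base <- voxelize(phantom_spec("ellipsoid", c(2, 1.5, 3)), cfg)
  flat <- voxelize(phantom_spec("bumpy_ellipsoid", c(2, 1.5, 3),
                                bump_amplitude = 0), cfg)
  sup2 <- voxelize(phantom_spec("superellipsoid", c(2, 1.5, 3),
                                exponent = 2), cfg)
  expect_identical(base$mask$data, flat$mask$data)
  expect_identical(base$mask$data, sup2$mask$data)
})

test_that("rotation preserves the measured volume up to discretization", {
  cfg <- voxel_config(pixel_spacing = c(0.1, 0.1), slice_thickness = 0.4,
                      slice_gap = 0, slice_offset = 0.05)
  plain <- voxelize(phantom_spec("ellipsoid", c(2, 1.5, 3)), cfg)
  turned <- voxelize(phantom_spec("ellipsoid", c(2, 1.5, 3),
                                  rotation = c(0.4, 0.3, 1.0)), cfg)
  v1 <- measure_volume(plain$mask, plain$series)$volume
  v2 <- measure_volume(turned$mask, turned$series)$volume
  expect_rel_equal(v2, v1, 0.02)
})

test_that("halving the grid moves the estimate closer to truth", {
  sp <- phantom_spec("ellipsoid", c(2, 1.8, 3.5))
  truth <- analytic_volume(sp)
  err <- vapply(c(1, 2, 4), function(f) {
    cfg <- voxel_config(pixel_spacing = c(0.4, 0.4) / f,
                        slice_thickness = 0.8 / f, slice_gap = 0,
                        slice_offset = 0.8 / f / 3)
    v <- voxelize(sp, cfg)
    abs(measure_volume(v$mask, v$series)$volume - truth)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("cohort generation is deterministic, truncated and sex-stratified", {
  cfg <- smoke_cohort(seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$phantoms, c2$phantoms)

  big <- generate_cohort(cohort_config(n_male = 40, n_female = 60, seed = 5))
  num <- big$truth[, c("age", "true_volume", "true_length", "l1_ap", "l1_tv",
                       "l1_area", "abd_ap", "abd_tv", "abd_circ",
                       "canal_area")]
  expect_true(all(num > 0))
  expect_true(all(big$truth$age > 18))
  expect_equal(table(big$truth$sex)[["male"]], 40)

  # phantom geometry honours the coupling rule exactly
  i <- 17
  ph <- big$phantoms[[i]]
  expect_equal(2 * ph$semi_axes[3], big$truth$true_length[i])
  expect_equal(analytic_volume(ph), big$truth$true_volume[i],
               tolerance = 1e-10)
})

test_that("degenerate and empty cohorts behave as documented", {
  empty <- generate_cohort(cohort_config(n_male = 0, n_female = 0))
  expect_identical(nrow(empty$truth), 0L)

  fixed <- generate_cohort(cohort_config(
    n_male = 5, n_female = 0, volume_sd = c(male = 0, female = 0),
    length_sd = c(male = 0, female = 0), seed = 2))
  expect_true(all(fixed$truth$true_volume == 223.5))
  expect_true(all(fixed$truth$true_length == 10))
})
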