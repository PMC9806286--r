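# Shared fixtures: small, fast phantoms and voxel grids used across tests.

# coarse grid keeps unit tests fast; acceptance tests choose their own
coarse_cfg <- function(...) {
  voxel_config(pixel_spacing = c(0.3, 0.3), slice_thickness = 0.6,
               slice_gap = 0.2, ...)
}

sphere_phantom <- function(r = 3) phantom_spec("ellipsoid", c(r, r, r))

# a mid-sized prolate spleen-like phantom
spleen_phantom <- function(volume = 200, length = 10) {
  cc <- length / 2
  a <- sqrt(3 * volume / (4 * pi * cc))
  phantom_spec("ellipsoid", c(a, a, cc))
}

# tiny cohort config for pipeline smoke tests
smoke_cohort <- function(n_male = 6, n_female = 9, seed = 7)
  cohort_config(n_male = n_male, n_female = n_female, seed = seed)

dice <- function(a, b) 2 * sum(a & b) / (sum(a != 0) + sum(b != 0))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
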